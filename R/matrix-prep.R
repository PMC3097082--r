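ALN_ALPHABET <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-", "?")

#' Construct an alignment object
#'
#' An alignment is stored as a character matrix (taxa x columns) over
#' the nucleotide/IUPAC alphabet plus \code{"-"} (gap) and \code{"?"}
#' (missing), validated case-insensitively.
#'
#' @param x Named character vector of equal-length gapped sequences, or
#'   a character matrix with taxa as rownames.
#' @return A matrix of class \code{alignment}.
#' @export
as_alignment <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else {
    stopifnot(is.character(x), !is.null(names(x)))
    lens <- nchar(x)
    if (length(unique(lens)) > 1L)
      stop("sequences have unequal lengths: ", paste(unique(lens), collapse = ", "))
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate taxon names")
  bad <- setdiff(unique(as.vector(m)), ALN_ALPHABET)
  if (length(bad) > 0)
    stop("invalid alignment characters: ", paste(bad, collapse = ", "))
  structure(m, class = c("alignment", "matrix"))
}

#' Read an aligned FASTA file
#' @param file Path to a FASTA file of equal-length sequences.
#' @return An \code{alignment}.
#' @export
read_alignment <- function(file) {
  seqs <- seqinr::read.fasta(file, as.string = TRUE, forceDNAtolower = FALSE)
  v <- vapply(seqs, function(s) as.character(s)[1L], character(1))
  names(v) <- names(seqs)
  as_alignment(v)
}

#' Write an alignment as FASTA
#' @param aln An \code{alignment}.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(aln, file) {
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = rownames(aln), file.out = file,
                      nbchar = 80)
  invisible(file)
}

#' Write a character matrix in relaxed PHYLIP format
#'
#' Relaxed names (no 10-character truncation), sequential layout.
#'
#' @param m Character matrix with taxa as rownames (an \code{alignment}
#'   or the matrix of a concatenated data set).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_phylip <- function(m, file) {
  seqs <- apply(unclass(m), 1, paste, collapse = "")
  pad <- max(nchar(rownames(m))) + 2L
  lines <- c(paste(nrow(m), ncol(m)),
             paste0(formatC(rownames(m), width = -pad), seqs))
  writeLines(lines, file)
  invisible(file)
}

# maximal gap runs of one sequence row: matrix with cols start, end
.gap_runs <- function(row) {
  r <- rle(row == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Simple indel coding of an alignment
#'
#' Codes gaps as binary presence/absence characters under the simple
#' coding strategy: every distinct interior gap (identical start and
#' end columns, terminal gaps excluded as missing data) observed in at
#' least one taxon becomes one character. A taxon scores 1 when it has
#' exactly that gap, 0 when no gap of its own overlaps the range, and
#' \code{"?"} when it has an overlapping gap of different extent
#' (including terminal gaps) or missing data anywhere in the range.
#' Characters are emitted in ascending (start, end) order.
#'
#' @param aln An \code{alignment} with >= 2 taxa.
#' @return A list of class \code{indel_matrix}: \code{matrix} (taxa x
#'   characters over \code{"0"}, \code{"1"}, \code{"?"}) and
#'   \code{descriptors} (data.frame with 1-based inclusive
#'   \code{start}, \code{end} columns per coded indel).
#' @examples
#' aln <- as_alignment(c(A = "ACGT", B = "A--T", C = "ACGT"))
#' code_indels(aln)$matrix
#' @export
code_indels <- function(aln) {
  aln <- as_alignment(unclass(aln))
  if (nrow(aln) < 2L) stop("need at least 2 taxa")
  L <- ncol(aln)
  runs <- lapply(seq_len(nrow(aln)), function(i) {
    r <- .gap_runs(aln[i, ])
    r[r[, "start"] > 1L & r[, "end"] < L, , drop = FALSE]  # interior only
  })
  all_runs <- unique(do.call(rbind, c(runs, list(cbind(start = integer(0), end = integer(0))))))
  if (nrow(all_runs) > 0)
    all_runs <- all_runs[order(all_runs[, "start"], all_runs[, "end"]), , drop = FALSE]
  n_char <- nrow(all_runs)
  m <- matrix("0", nrow(aln), n_char, dimnames = list(rownames(aln), NULL))
  if (n_char > 0) {
    for (i in seq_len(nrow(aln))) {
      row <- aln[i, ]
      own <- .gap_runs(row)   # all runs, terminal included
      for (ch in seq_len(n_char)) {
        s <- all_runs[ch, "start"]; e <- all_runs[ch, "end"]
        exact <- nrow(own) > 0 &&
          any(own[, "start"] == s & own[, "end"] == e &
                (own[, "start"] > 1L & own[, "end"] < L))
        if (exact) {
          m[i, ch] <- "1"
        } else if (any(row[s:e] == "?")) {
          m[i, ch] <- "?"
        } else if (nrow(own) > 0 && any(own[, "start"] <= e & own[, "end"] >= s)) {
          m[i, ch] <- "?"   # overlapping gap of different extent, or terminal gap
        }
      }
    }
  }
  structure(list(matrix = m,
                 descriptors = data.frame(start = as.integer(all_runs[, "start"]),
                                          end = as.integer(all_runs[, "end"]))),
            class = "indel_matrix")
}

#' @export
print.indel_matrix <- function(x, ...) {
  cat(sprintf("<indel matrix> %d taxa, %d coded gap character(s)\n",
              nrow(x$matrix), ncol(x$matrix)))
  if (ncol(x$matrix) > 0) print(cbind(x$descriptors, t(x$matrix)))
  invisible(x)
}

#' Write coded indel characters as TSV
#' @param im An \code{indel_matrix}.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_indel_tsv <- function(im, file) {
  stopifnot(inherits(im, "indel_matrix"))
  df <- data.frame(taxon = rownames(im$matrix), im$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(im$matrix) > 0)
    names(df)[-1] <- paste0("indel_", im$descriptors$start, "_", im$descriptors$end)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Truncate alignment ends
#'
#' Drops \code{lead} leading and \code{trail} trailing columns - the
#' usual trimming of conserved primer-adjacent regions at the 5' and 3'
#' ends before concatenation.
#'
#' @param aln An \code{alignment}.
#' @param lead,trail Non-negative column counts; their sum must be less
#'   than the alignment length.
#' @return The truncated \code{alignment} (columns lead+1 .. L-trail).
#' @export
truncate_ends <- function(aln, lead = 0L, trail = 0L) {
  aln <- as_alignment(unclass(aln))
  L <- ncol(aln)
  stopifnot(lead >= 0, trail >= 0)
  if (lead + trail >= L)
    stop("over-truncation: lead + trail (", lead + trail, ") >= length (", L, ")")
  as_alignment(aln[, seq(lead + 1L, L - trail), drop = FALSE])
}

#' Map ungapped reference positions to alignment columns
#'
#' Converts a 1-based inclusive position range on the ungapped sequence
#' of a reference taxon (e.g. "position 599-671 of accession X") into
#' the corresponding alignment columns. Gaps in the reference do not
#' consume positions.
#'
#' @param aln An \code{alignment}.
#' @param ref_taxon Name of the reference taxon.
#' @param start,end 1-based inclusive ungapped positions.
#' @return Integer vector \code{c(from, to)} of alignment columns.
#' @examples
#' aln <- as_alignment(c(R = "AC-GT", S = "ACAGT"))
#' map_reference_positions(aln, "R", 3, 4)  # columns 4..5
#' @export
map_reference_positions <- function(aln, ref_taxon, start, end) {
  aln <- as_alignment(unclass(aln))
  if (!ref_taxon %in% rownames(aln)) stop("reference taxon '", ref_taxon, "' not present")
  stopifnot(start >= 1, start <= end)
  row <- aln[ref_taxon, ]
  cols <- which(row != "-")
  if (end > length(cols))
    stop("position ", end, " beyond ungapped reference length ", length(cols))
  c(from = cols[start], to = cols[end])
}

#' Exclude column ranges from an alignment
#'
#' Removes the stated columns from all taxa; overlapping ranges are
#' merged first. Excluding every column yields a zero-length alignment
#' (allowed, with a message).
#'
#' @param aln An \code{alignment}.
#' @param ranges List of \code{c(from, to)} 1-based inclusive column
#'   ranges (or a two-column matrix).
#' @return The reduced \code{alignment}.
#' @export
exclude_columns <- function(aln, ranges) {
  aln <- as_alignment(unclass(aln))
  if (is.matrix(ranges)) ranges <- lapply(seq_len(nrow(ranges)), function(i) ranges[i, ])
  if (length(ranges) == 0L) return(aln)
  L <- ncol(aln)
  drop <- integer(0)
  for (r in ranges) {
    stopifnot(length(r) == 2L)
    if (r[1] < 1 || r[2] > L || r[1] > r[2])
      stop("column range out of bounds: ", r[1], "-", r[2], " (length ", L, ")")
    drop <- union(drop, seq(r[1], r[2]))
  }
  keep <- setdiff(seq_len(L), drop)
  if (length(keep) == 0L) message("all columns excluded; zero-length alignment")
  structure(aln[, keep, drop = FALSE], class = c("alignment", "matrix"))
}

#' Concatenate character matrices into one supermatrix
#'
#' Concatenates alignments and/or coded indel matrices column-wise. The
#' taxon set is the union; a taxon absent from a block is filled with
#' \code{"?"} across that block (a taxon without an accession for one
#' marker is simply missing data there). A partition table records the
#' block boundaries and data type, so the binary indel partition can be
#' analysed under its own model downstream.
#'
#' @param blocks List of \code{alignment} and/or \code{indel_matrix}
#'   objects (at least one).
#' @param names Optional block names.
#' @return A list of class \code{concat_matrix}: \code{matrix} (taxa x
#'   total columns) and \code{partition} (data.frame: block, start,
#'   end, type).
#' @export
concatenate_matrices <- function(blocks, names = NULL) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  mats <- lapply(blocks, function(b) {
    if (inherits(b, "indel_matrix")) b$matrix else unclass(as_alignment(unclass(b)))
  })
  types <- vapply(blocks, function(b)
    if (inherits(b, "indel_matrix")) "binary" else "nucleotide", character(1))
  if (is.null(names)) names <- paste0("block", seq_along(blocks))
  taxa <- sort(unique(unlist(lapply(mats, rownames))))
  widths <- vapply(mats, ncol, integer(1))
  out <- matrix("?", length(taxa), sum(widths), dimnames = list(taxa, NULL))
  at <- 0L
  part <- data.frame(block = names, start = integer(length(mats)),
                     end = integer(length(mats)), type = types,
                     stringsAsFactors = FALSE)
  for (i in seq_along(mats)) {
    w <- widths[i]
    part$start[i] <- at + 1L
    part$end[i] <- at + w
    if (w > 0)
      out[rownames(mats[[i]]), seq(at + 1L, at + w)] <- mats[[i]]
    at <- at + w
  }
  structure(list(matrix = out, partition = part), class = "concat_matrix")
}

#' @export
print.concat_matrix <- function(x, ...) {
  cat(sprintf("<concatenated matrix> %d taxa x %d columns, %d block(s)\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$partition)))
  print(x$partition)
  invisible(x)
}

#' Write a partition table
#'
#' Simple text format: one line per block with name, start, end, type.
#'
#' @param cm A \code{concat_matrix}.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_partition_table <- function(cm, file) {
  stopifnot(inherits(cm, "concat_matrix"))
  utils::write.table(cm$partition, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
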