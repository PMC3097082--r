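#' Parse a ploidal-level table
#'
#' Reads a table with at least a taxon column and a ploidy column
#' holding strings in the style of cytological compilations:
#' \code{"8x, 10x"}, \code{"2x, 3x, 4x, 5x, aneuploids"}, \code{"8x?"}
#' (uncertain count), \code{"(2x), 4x, (6x)"} (parenthesized reports),
#' or empty (no report). Bracketed citations are stripped before
#' parsing. Additional columns (clade, style shape, anther shape) are
#' carried through.
#'
#' @param x Path to a TSV file with a header row, or a data.frame.
#' @param taxon_col,ploidy_col Column names (defaults \code{"taxon"} and
#'   \code{"ploidy"}).
#' @return A data.frame of class \code{ploidy_table}: one row per taxon
#'   with list-columns \code{levels}, \code{uncertain_levels},
#'   \code{parenthesized_levels} (integer multiples of the base number
#'   x) and logicals \code{aneuploid}, \code{unknown}.
#' @examples
#' df <- data.frame(taxon = c("sp1", "sp2"), ploidy = c("8x, 10x", ""))
#' parse_ploidy_table(df)$levels
#' @export
parse_ploidy_table <- function(x, taxon_col = "taxon", ploidy_col = "ploidy") {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.delim(x, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, na.strings = NULL,
                           check.names = FALSE)
  }
  stopifnot(is.data.frame(x))
  if (!all(c(taxon_col, ploidy_col) %in% names(x)))
    stop("table must have columns '", taxon_col, "' and '", ploidy_col, "'")
  out <- x
  names(out)[names(out) == taxon_col] <- "taxon"
  names(out)[names(out) == ploidy_col] <- "ploidy"
  parsed <- lapply(seq_len(nrow(out)), function(i)
    .parse_ploidy_string(out$ploidy[i], out$taxon[i]))
  out$levels <- lapply(parsed, `[[`, "levels")
  out$uncertain_levels <- lapply(parsed, `[[`, "uncertain")
  out$parenthesized_levels <- lapply(parsed, `[[`, "paren")
  out$aneuploid <- vapply(parsed, `[[`, logical(1), "aneuploid")
  out$unknown <- vapply(parsed, `[[`, logical(1), "unknown")
  class(out) <- c("ploidy_table", "data.frame")
  out
}

.parse_ploidy_string <- function(s, taxon = "<unknown>") {
  if (is.na(s)) s <- ""
  s <- gsub("\\[[^]]*\\]", "", s)   # strip bracketed citations
  s <- trimws(s)
  res <- list(levels = integer(0), uncertain = integer(0), paren = integer(0),
              aneuploid = FALSE, unknown = FALSE)
  if (!nzchar(s)) {
    res$unknown <- TRUE
    return(res)
  }
  tokens <- trimws(strsplit(s, ",")[[1]])
  tokens <- tokens[nzchar(tokens)]
  for (tok in tokens) {
    if (grepl("^aneuploids?$", tok, ignore.case = TRUE)) {
      res$aneuploid <- TRUE
    } else if (grepl("^\\(\\s*[0-9]+\\s*x\\s*\\)$", tok, ignore.case = TRUE)) {
      res$paren <- c(res$paren, as.integer(sub("^\\(\\s*([0-9]+).*", "\\1", tok)))
    } else if (grepl("^[0-9]+\\s*x\\s*\\?$", tok, ignore.case = TRUE)) {
      res$uncertain <- c(res$uncertain, as.integer(sub("^([0-9]+).*", "\\1", tok)))
    } else if (grepl("^[0-9]+\\s*x$", tok, ignore.case = TRUE)) {
      res$levels <- c(res$levels, as.integer(sub("^([0-9]+).*", "\\1", tok)))
    } else {
      stop("unparseable ploidy token '", tok, "' for taxon '", taxon, "'")
    }
  }
  lv <- c(res$levels, res$uncertain, res$paren)
  if (any(lv < 2)) stop("ploidal level below 2x for taxon '", taxon, "'")
  res
}

#' Is a taxon polyploid?
#'
#' A taxon counts as polyploid when any reported ploidal level is
#' triploid or higher (>= 3x). Uncertain (\code{"8x?"}) and
#' parenthesized levels count by default, since such reports are still
#' treated as polyploidy-relevant; \code{include_uncertain = FALSE}
#' gives a strict mode using firm reports only. Unknown ploidy is
#' conservatively non-polyploid.
#'
#' @param record One row of a \code{ploidy_table} (or the whole table,
#'   giving a logical vector).
#' @param include_uncertain Count uncertain and parenthesized levels?
#' @return Logical.
#' @export
is_polyploid <- function(record, include_uncertain = TRUE) {
  stopifnot(inherits(record, "ploidy_table") || is.data.frame(record))
  vapply(seq_len(nrow(record)), function(i) {
    lv <- record$levels[[i]]
    if (include_uncertain)
      lv <- c(lv, record$uncertain_levels[[i]], record$parenthesized_levels[[i]])
    length(lv) > 0 && any(lv >= 3)
  }, logical(1))
}

#' Flag incongruence events as allopolyploidy candidates
#'
#' An event is flagged when any of its involved taxa is polyploid.
#' Hybridization followed by genome doubling (allopolyploidy) predicts
#' exactly this signature: a taxon with an elevated ploidal level whose
#' nuclear and chloroplast placements contradict each other. Taxa
#' missing from the table are treated as unknown ploidy (and reported
#' in the \code{missing_taxa} attribute).
#'
#' @param events An \code{incongruence_set} from [cluster_events()].
#' @param records A \code{ploidy_table} from [parse_ploidy_table()].
#' @param include_uncertain Passed to [is_polyploid()].
#' @return The events, each annotated with \code{polyploid_candidate}
#'   (logical) and \code{evidence} (data.frame of polyploid involved
#'   taxa and their reported levels).
#' @export
flag_events <- function(events, records, include_uncertain = TRUE) {
  stopifnot(inherits(events, "incongruence_set"))
  if (!inherits(records, "ploidy_table")) records <- parse_ploidy_table(records)
  poly <- is_polyploid(records, include_uncertain)
  missing_all <- character(0)
  for (i in seq_along(events)) {
    ev <- events[[i]]
    idx <- match(ev$involved_taxa, records$taxon)
    missing_all <- c(missing_all, ev$involved_taxa[is.na(idx)])
    hit <- which(!is.na(idx) & poly[idx])
    ev$polyploid_candidate <- length(hit) > 0
    ev$evidence <- data.frame(
      taxon = ev$involved_taxa[hit],
      levels = vapply(idx[hit], function(j) {
        lv <- c(records$levels[[j]],
                if (include_uncertain) c(records$uncertain_levels[[j]],
                                         records$parenthesized_levels[[j]]))
        paste0(sort(unique(lv)), "x", collapse = ", ")
      }, character(1)),
      stringsAsFactors = FALSE)
    events[[i]] <- ev
  }
  attr(events, "missing_taxa") <- sort(unique(missing_all))
  events
}
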