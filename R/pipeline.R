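#' Assemble a pipeline configuration
#'
#' Validates and freezes the inputs of a full discordance run. Inputs
#' may be file paths (Newick trees, ploidy TSV) or in-memory objects.
#'
#' @param tree1,tree2 Tree 1 (e.g. nuclear) and tree 2 (e.g.
#'   chloroplast): paths or \code{phylo}.
#' @param ploidy Optional ploidy table: path, data.frame or
#'   \code{ploidy_table}.
#' @param thr1,thr2 Support thresholds in \[0, 1\] for conflict
#'   detection (defaults 0.95).
#' @param include_uncertain Count uncertain/parenthesized ploidy levels
#'   (default TRUE).
#' @param characters Optional taxa x characters matrix (or path to a
#'   TSV with a taxon column) for ancestral-state reconstruction.
#' @param asr_character Column of \code{characters} to reconstruct.
#' @param asr_models Mk model kinds to fit (default ER, SYM, ARD).
#' @param consensus_cutoff When \code{tree1}/\code{tree2} are
#'   multi-tree samples, the majority-rule cutoff used to summarise
#'   them first (default 0.5).
#' @param seed Integer seed stamped into the report (the pipeline
#'   itself is deterministic).
#' @param out_dir Optional output directory for reports.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(tree1, tree2, ploidy = NULL,
                            thr1 = 0.95, thr2 = 0.95,
                            include_uncertain = TRUE,
                            characters = NULL, asr_character = NULL,
                            asr_models = c("ER", "SYM", "ARD"),
                            consensus_cutoff = 0.5,
                            seed = NULL, out_dir = NULL) {
  stopifnot(thr1 >= 0, thr1 <= 1, thr2 >= 0, thr2 <= 1)
  load_tree <- function(x) {
    if (is.character(x)) x <- read_trees(x)
    if (inherits(x, "multiPhylo") || (is.list(x) && !inherits(x, "phylo")))
      x <- majority_consensus(x, consensus_cutoff)
    validate_tree(x)
    x
  }
  if (!is.null(ploidy) && !inherits(ploidy, "ploidy_table"))
    ploidy <- parse_ploidy_table(ploidy)
  if (is.character(characters) && length(characters) == 1L) {
    tab <- utils::read.delim(characters, sep = "\t", stringsAsFactors = FALSE)
    characters <- as.matrix(tab[, setdiff(names(tab), "taxon"), drop = FALSE])
    rownames(characters) <- tab$taxon
  }
  structure(list(tree1 = load_tree(tree1), tree2 = load_tree(tree2),
                 ploidy = ploidy, thr1 = thr1, thr2 = thr2,
                 include_uncertain = include_uncertain,
                 characters = characters, asr_character = asr_character,
                 asr_models = match.arg(asr_models, c("ER", "SYM", "ARD"),
                                        several.ok = TRUE),
                 consensus_cutoff = consensus_cutoff,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full discordance pipeline
#'
#' Executes conflict detection, event clustering, ploidy flagging and
#' (optionally) ancestral-state reconstruction, and writes
#' machine-readable reports. Identical configuration and inputs give
#' identical outputs.
#'
#' Stages: restrict the two trees to shared taxa; find well-supported
#' conflicting split pairs; cluster them into incongruence events; flag
#' events whose involved taxa include polyploids; list clades supported
#' in both trees; fit the requested Mk models to the chosen character
#' on tree 1 (polytomies resolved with zero-length branches), pick a
#' model by likelihood-ratio tests and reconstruct per-node scaled
#' state likelihoods.
#'
#' @param config A \code{pipeline_config}.
#' @return A \code{pipeline_report} list; when \code{out_dir} is set,
#'   \code{report.json}, \code{events.tsv} and \code{summary.txt} are
#'   written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "conflict detection"
  report <- tryCatch({
    pairs <- find_conflicting_pairs(config$tree1, config$tree2,
                                    config$thr1, config$thr2)
    stage <- "event clustering"
    events <- cluster_events(pairs, config$tree1, config$tree2)
    stage <- "ploidy flagging"
    if (!is.null(config$ploidy))
      events <- flag_events(events, config$ploidy, config$include_uncertain)
    stage <- "shared clades"
    shared <- shared_supported_clades(config$tree1, config$tree2,
                                      min(config$thr1, config$thr2))
    asr <- NULL
    if (!is.null(config$characters) && !is.null(config$asr_character)) {
      stage <- "ancestral state reconstruction"
      x <- config$characters[, config$asr_character]
      names(x) <- rownames(config$characters)
      tr <- resolve_polytomies(config$tree1)
      x <- x[names(x) %in% tr$tip.label]
      fits <- lapply(config$asr_models, function(kind)
        fit_mk(tr, x[tr$tip.label], kind))
      names(fits) <- config$asr_models
      lrt <- list()
      if (all(c("ER", "SYM") %in% names(fits)))
        lrt$ER_vs_SYM <- mk_lrt(fits$ER, fits$SYM)
      if (all(c("SYM", "ARD") %in% names(fits)))
        lrt$SYM_vs_ARD <- mk_lrt(fits$SYM, fits$ARD)
      chosen <- .choose_model(fits, lrt)
      asr <- list(fits = fits, lrt = lrt, chosen = chosen,
                  scaled_likelihoods = ancestral_states(fits[[chosen]]))
    }
    list(version = as.character(utils::packageVersion("phyloconflict")),
         seed = config$seed,
         params = list(thr1 = config$thr1, thr2 = config$thr2,
                       include_uncertain = config$include_uncertain,
                       consensus_cutoff = config$consensus_cutoff),
         n_shared_taxa = length(intersect(config$tree1$tip.label,
                                          config$tree2$tip.label)),
         n_conflict_pairs = length(pairs),
         n_events = length(events),
         events = events,
         n_flagged = sum(vapply(events, function(e)
           isTRUE(e$polyploid_candidate), logical(1))),
         shared_clades = shared,
         asr = asr)
  }, error = function(e) {
    if (!is.null(config$out_dir))
      unlink(file.path(config$out_dir,
                       c("report.json", "events.tsv", "summary.txt")))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# sequential LRT at the 5% level: upgrade ER -> SYM -> ARD while significant
.choose_model <- function(fits, lrt, alpha = 0.05) {
  chosen <- names(fits)[1L]
  if (!is.null(lrt$ER_vs_SYM) && lrt$ER_vs_SYM$p.value < alpha) chosen <- "SYM"
  if (chosen == "SYM" && !is.null(lrt$SYM_vs_ARD) &&
      lrt$SYM_vs_ARD$p.value < alpha) chosen <- "ARD"
  chosen
}

#' Write pipeline reports to a directory
#'
#' Emits \code{report.json} (versioned, machine-readable),
#' \code{events.tsv} (one row per incongruence event) and
#' \code{summary.txt} (human-readable).
#'
#' @param report A \code{pipeline_report}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev_df <- .events_df(report$events)
  js <- list(schema = "phyloconflict-report/1",
             version = report$version, seed = report$seed,
             params = report$params,
             n_shared_taxa = report$n_shared_taxa,
             n_conflict_pairs = report$n_conflict_pairs,
             n_events = report$n_events, n_flagged = report$n_flagged,
             events = lapply(seq_along(report$events), function(i) {
               e <- report$events[[i]]
               list(id = i, rogue_clade = e$rogue_clade,
                    involved_taxa = e$involved_taxa,
                    n_pairs = length(e$attributed_pairs),
                    polyploid_candidate = isTRUE(e$polyploid_candidate),
                    evidence = if (!is.null(e$evidence)) e$evidence)
             }),
             shared_clades = lapply(report$shared_clades, function(s)
               list(taxa = s$taxa, support = s$support)))
  if (!is.null(report$asr)) {
    js$asr <- list(
      models = lapply(report$asr$fits, function(f)
        list(kind = f$kind, loglik = f$loglik, df = f$df,
             rates = as.list(f$rates))),
      lrt = lapply(report$asr$lrt, function(l)
        list(statistic = l$statistic, df = l$df, p = l$p.value)),
      chosen = report$asr$chosen,
      scaled_likelihoods = apply(unclass(report$asr$scaled_likelihoods), 1,
                                 as.list, simplify = FALSE))
  }
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  utils::write.table(ev_df, file.path(dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(utils::capture.output(print(report)), file.path(dir, "summary.txt"))
  invisible(dir)
}

.events_df <- function(events) {
  if (length(events) == 0L)
    return(data.frame(id = integer(0), rogue_clade = character(0),
                      involved_taxa = character(0), n_pairs = integer(0),
                      polyploid_candidate = logical(0)))
  data.frame(
    id = seq_along(events),
    rogue_clade = vapply(events, function(e)
      paste(e$rogue_clade, collapse = ","), character(1)),
    involved_taxa = vapply(events, function(e)
      paste(e$involved_taxa, collapse = ","), character(1)),
    n_pairs = vapply(events, function(e) length(e$attributed_pairs), integer(1)),
    polyploid_candidate = vapply(events, function(e)
      isTRUE(e$polyploid_candidate), logical(1)),
    stringsAsFactors = FALSE)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("phyloconflict pipeline report (schema v1, package", x$version, ")\n")
  cat(sprintf("  shared taxa: %d | conflicting pairs: %d | events: %d | flagged: %d\n",
              x$n_shared_taxa, x$n_conflict_pairs, x$n_events, x$n_flagged))
  print(x$events)
  cat(sprintf("  clades supported in both trees: %d\n", length(x$shared_clades)))
  if (!is.null(x$asr)) {
    cat("  ancestral-state reconstruction:\n")
    for (nm in names(x$asr$fits))
      cat(sprintf("    %s: logL = %.4f (df %d)\n", nm,
                  x$asr$fits[[nm]]$loglik, x$asr$fits[[nm]]$df))
    for (nm in names(x$asr$lrt))
      cat(sprintf("    LRT %s: p = %.4g\n", nm, x$asr$lrt[[nm]]$p.value))
    cat("    chosen model:", x$asr$chosen, "\n")
  }
  invisible(x)
}
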