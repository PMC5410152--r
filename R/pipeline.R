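#' Run the full developmental-sequence analysis pipeline
#'
#' Orchestrates one analysis track end to end: encode the timelines
#' (continuous + decile-binned, or event-pair), map the characters on the
#' two hypothesis topologies, run the heuristic parsimony search with
#' consensus, reconstruct ancestral states, detect heterochronies (root-CI
#' criterion for continuous data, event-pair cracking otherwise), and run
#' the Templeton test between the hypotheses.  All outputs are written to
#' `outdir` together with a run manifest.
#'
#' @param config A named list (or path to a YAML file, read with the
#'   `yaml` package) with elements: `timeline` (path or
#'   `timeline_matrix`), `trees` (named list of two newick paths or
#'   `phylo` objects, e.g. `molecular` and `morphological`), `mode`
#'   (`"continuous"` or `"eventpair"`), `ordered` (logical),
#'   `branch_lengths` (`"unit"` or `"calibrated"`), `calibrations`
#'   (path or data frame, when calibrated), `reference` (`"lepidosaur"`
#'   or `"squamate"`), `outgroup` (tip label, optional), `outdir`,
#'   `seed`, and optional `replicates`/`hold` for the search.
#' @return Invisibly, a list with the assembled results (`characters`,
#'   `scores`, `search`, `consensus`, `ancestral`, `report`,
#'   `templeton`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config needs the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  defaults <- list(mode = "eventpair", ordered = FALSE,
                   branch_lengths = "unit", reference = "lepidosaur",
                   outgroup = NULL, seed = 1L, replicates = 10L,
                   hold = 10L, outdir = NULL)
  config <- modifyList(defaults, config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  tl <- stage("load timelines",
    if (inherits(config$timeline, "timeline_matrix")) config$timeline
    else read_timeline(config$timeline))
  trees <- stage("load trees", lapply(config$trees, function(t) {
    tr <- if (inherits(t, "phylo")) name_internal_nodes(t)
          else read_newick_tree(t, taxa = tl$species)
    if (!is.null(config$outgroup) && config$outgroup %in% tr$tip.label)
      tr <- name_internal_nodes(
        ape::root(tr, outgroup = config$outgroup, resolve.root = TRUE))
    tr
  }))
  trees <- stage("branch lengths", lapply(trees, function(tr) {
    if (config$branch_lengths == "unit") unit_branch_lengths(tr)
    else {
      cal <- if (is.data.frame(config$calibrations)) config$calibrations
             else read_calibrations(config$calibrations)
      calibrate_branch_lengths(tr, cal)
    }
  }))
  cont <- stage("continuous scaling", to_continuous(tl))
  cmx <- stage("encode", if (config$mode == "continuous")
    discretize(cont) else event_pair_encode(tl))
  cmx$ordered <- isTRUE(config$ordered)

  scores <- stage("map on hypotheses",
    lapply(trees, function(tr) tree_length(cmx, tr, config$ordered)))
  search <- stage("heuristic search",
    heuristic_search(cmx, ordered = config$ordered,
                     replicates = config$replicates, hold = config$hold,
                     seed = config$seed))
  cons <- stage("consensus", list(
    strict = consensus_tree(search$trees, "strict"),
    majority50 = consensus_tree(search$trees, "majority50")))

  anc <- list(); report <- empty_heterochrony_report()
  if (config$mode == "continuous") {
    anc <- stage("ancestral (squared-change + root CI)", lapply(
      trees, function(tr) {
        per_event <- lapply(setNames(cont$events, cont$events),
          function(ev) {
            v <- setNames(cont$values[, ev], cont$species)
            if (sum(!is.na(v[tr$tip.label])) < 3L) return(NULL)
            squared_change_reconstruct(v, tr)
          })
        mapped_score <- sum(vapply(per_event, function(z)
          if (is.null(z)) 0 else z$score, 0))
        list(per_event = per_event, mapped_score = mapped_score)
      }))
    report <- stage("continuous heterochrony", do.call(rbind, lapply(
      names(trees), function(nm) {
        rp <- flag_continuous_heterochrony(
          cont, trees[[nm]],
          reference = config$reference, outgroup = config$outgroup)
        if (nrow(rp)) rp$tree <- nm else rp$tree <- character(0)
        rp
      })))
  } else {
    anc <- stage("ancestral (MP + cracking)", lapply(trees, function(tr)
      mp_reconstruct(cmx, tr, ordered = config$ordered)))
    report <- stage("event-pair cracking", do.call(rbind, lapply(
      names(trees), function(nm) {
        rp <- crack_tree(anc[[nm]])$report
        if (nrow(rp)) rp$tree <- nm else rp$tree <- character(0)
        rp
      })))
  }
  class(report) <- c("heterochrony_report", "data.frame")

  tt <- stage("Templeton test",
    templeton_test(cmx, trees[[1L]], trees[[2L]], config$ordered))

  manifest <- list(
    package = "heterochron",
    version = as.character(packageVersion("heterochron")),
    r_version = R.version.string,
    seed = config$seed,
    mode = config$mode, ordered = config$ordered,
    branch_lengths = config$branch_lengths,
    reference = config$reference,
    n_species = length(tl$species), n_events = length(tl$events),
    n_characters = ncol(cmx$states),
    best_length = search$best_length,
    n_best_trees = length(search$trees),
    templeton_p = tt$p)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(...) file.path(config$outdir, ...)
    write_character_matrix(cmx, "nexus", file = out("characters.nex"))
    ape::write.tree(do.call(c, search$trees), out("best_trees.nwk"))
    ape::write.tree(cons$strict, out("consensus_strict.nwk"))
    ape::write.tree(cons$majority50, out("consensus_majority50.nwk"))
    jsonlite::write_json(
      list(per_tree = lapply(scores, function(s)
             list(total = s$total, ci = s$ci, ri = s$ri)),
           search = list(best_length = search$best_length,
                         n_trees = length(search$trees)),
           templeton = list(p = tt$p, n_nonzero = tt$n_nonzero)),
      out("scores.json"), auto_unbox = TRUE, digits = NA)
    write.table(report, out("heterochrony_report.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(characters = cmx, continuous = cont, scores = scores,
                 search = search, consensus = cons, ancestral = anc,
                 report = report, templeton = tt, manifest = manifest))
}
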