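# The two-stage candidate screen: rank by binding score and keep the
# top set, then rescore the survivors by hydration energy and apply the
# solubility threshold. Binding scores follow the Rosetta convention:
# lower is better.

#' Screen configuration
#'
#' Defaults mirror the reference pipeline: keep the 100 top-scored
#' candidates out of an expected pool of 1000, then keep only those
#' with hydration energy strictly below -42 kcal/mol.
#'
#' @param stage1_keep number of candidates surviving stage 1.
#' @param stage1_pool advisory expected input size.
#' @param hydration_threshold stage-2 threshold, kcal/mol; survival
#'   requires hydration strictly lower than this.
#' @param tie_break tie rule for equal binding scores; only
#'   `"id"` (lexicographic) is implemented.
#' @return object of class `screen_config`
#' @export
screen_config <- function(stage1_keep = 100L, stage1_pool = 1000L,
                          hydration_threshold = -42, tie_break = "id") {
  stopifnot(stage1_keep >= 1, is.finite(hydration_threshold),
            identical(tie_break, "id"))
  structure(list(stage1_keep = as.integer(stage1_keep),
                 stage1_pool = as.integer(stage1_pool),
                 hydration_threshold = hydration_threshold,
                 tie_break = tie_break),
            class = "screen_config")
}

#' Stage 1: rank candidates by binding score
#'
#' Returns the `keep` candidates with the lowest binding score, sorted
#' ascending; ties are broken lexicographically by id so runs are
#' reproducible regardless of input order.
#'
#' @param candidates candidate data frame (`id`, `binding_score`, ...).
#' @param keep how many to keep; if `keep >= nrow`, all are returned.
#' @return the surviving rows, sorted.
#' @export
rank_by_binding <- function(candidates, keep) {
  stopifnot(is.data.frame(candidates), keep >= 1)
  miss <- is.na(candidates$binding_score)
  if (any(miss))
    stop("missing binding score for candidate(s): ",
         paste(candidates$id[miss], collapse = ", "), call. = FALSE)
  ord <- order(candidates$binding_score, candidates$id)
  out <- candidates[ord, , drop = FALSE]
  out <- utils::head(out, keep)
  rownames(out) <- NULL
  out
}

#' Stage 2: filter candidates by hydration energy
#'
#' Keeps candidates whose hydration energy is strictly lower than the
#' threshold ("lower than" is read as a strict inequality; a candidate
#' at exactly the threshold is excluded). Input order is preserved.
#'
#' @param candidates candidate data frame with `hydration` populated.
#' @param threshold kcal/mol.
#' @return the surviving rows.
#' @export
filter_by_hydration <- function(candidates, threshold = -42) {
  stopifnot(is.data.frame(candidates), is.finite(threshold))
  miss <- is.na(candidates$hydration)
  if (any(miss))
    stop("missing hydration energy for candidate(s): ",
         paste(candidates$id[miss], collapse = ", "), call. = FALSE)
  out <- candidates[candidates$hydration < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the two-stage screen
#'
#' Stage 1 ranks by binding score and keeps the top `stage1_keep`;
#' hydration energies are then computed only for the stage-1 survivors
#' (matching the reference order of operations) and stage 2 applies the
#' strict hydration threshold. Candidates whose structures cannot be
#' resolved are dropped from stage 2 with a logged reason.
#'
#' @param candidates candidate data frame.
#' @param config a [screen_config].
#' @param params a [solvation_params] for the hydration rescoring.
#' @param structures structure resolver, as in [hydration_profile()].
#'   May be `NULL` when `candidates$hydration` is already populated.
#' @param mode hydration mode, `"fast"` or `"oracle"`.
#' @return object of class `screen_report`: list with `stage1`,
#'   `stage2` (candidate data frames), `dropped` (id + reason),
#'   `counts`, and the echoed `config`.
#' @export
run_screen <- function(candidates, config = screen_config(),
                       params = default_solvation_params(),
                       structures = NULL, mode = "fast") {
  stopifnot(is.data.frame(candidates), inherits(config, "screen_config"))
  if (nrow(candidates) == 0L) {
    empty <- candidates
    return(structure(list(stage1 = empty, stage2 = empty,
                          dropped = data.frame(id = character(),
                                               message = character()),
                          counts = c(input = 0L, stage1 = 0L, stage2 = 0L),
                          config = config), class = "screen_report"))
  }
  if (anyDuplicated(candidates$id))
    stop("candidate ids are not unique", call. = FALSE)
  stage1 <- rank_by_binding(candidates, config$stage1_keep)
  if (is.null(structures)) {
    scored <- stage1
    dropped <- data.frame(id = character(), message = character(),
                          stringsAsFactors = FALSE)
  } else {
    scored <- hydration_profile(stage1, params, structures, mode = mode)
    dropped <- attr(scored, "errors")
    scored <- scored[!is.na(scored$hydration), , drop = FALSE]
  }
  stage2 <- filter_by_hydration(scored, config$hydration_threshold)
  structure(list(stage1 = stage1, stage2 = stage2, dropped = dropped,
                 counts = c(input = nrow(candidates),
                            stage1 = nrow(stage1), stage2 = nrow(stage2)),
                 config = config),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Two-stage miniprotein screen\n")
  cat(sprintf("  input: %d candidates\n", x$counts["input"]))
  cat(sprintf("  stage 1 (binding rank, keep %d): %d survivors\n",
              x$config$stage1_keep, x$counts["stage1"]))
  cat(sprintf("  stage 2 (hydration < %g kcal/mol): %d survivors\n",
              x$config$hydration_threshold, x$counts["stage2"]))
  if (nrow(x$dropped))
    cat("  dropped (unresolvable structures):", nrow(x$dropped), "\n")
  invisible(x)
}

#' Write a screen report (JSON + survivor TSVs)
#'
#' @param report a `screen_report`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_screen_report <- function(report, dir) {
  stopifnot(inherits(report, "screen_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_candidates(report$stage1, file.path(dir, "stage1_survivors.tsv"))
  write_candidates(report$stage2, file.path(dir, "stage2_survivors.tsv"))
  jsonlite::write_json(list(
    counts = as.list(report$counts),
    config = unclass(report$config),
    dropped = report$dropped,
    stage2_ids = report$stage2$id), file.path(dir, "screen_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
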