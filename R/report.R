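#' Benjamini-Hochberg FDR-adjusted q-values
#'
#' Step-up adjustment: over ascending order statistics,
#' \eqn{q_{(i)} = \min(p_{(i)} m / i, q_{(i+1)})}, returned in input
#' order. Implemented via [stats::p.adjust()].
#'
#' @param pvals p-values in (0, 1\].
#' @return q-values aligned to the input order; empty input gives an empty
#'   result.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals) | pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Analysis configuration for the two-sample MR pipeline
#'
#' Collects every threshold and seed of a run in one declarative object so
#' that a run is fully reproducible from its configuration. Can be
#' populated from a YAML file with [read_mr_config()].
#'
#' @param p_threshold,r2_threshold,window_kb instrument-selection settings
#'   (see [clump_config()]).
#' @param palindrome_eaf_window palindromic-SNP frequency window
#'   (see [harmonize()]).
#' @param se_mode Wald-ratio Delta-method order.
#' @param boot_reps bootstrap replicates for the median estimators.
#' @param presso_nsim MR-PRESSO null simulations.
#' @param seed root integer seed; all stage seeds derive from it.
#' @param reverse also run each outcome as exposure against the primary
#'   exposure as outcome.
#' @return An `mr_config` list.
#' @export
mr_config <- function(p_threshold = 5e-7, r2_threshold = 0.01,
                      window_kb = 10000, palindrome_eaf_window = 0.08,
                      se_mode = "first_order", boot_reps = 1000,
                      presso_nsim = 1000, seed = 1L, reverse = FALSE) {
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb,
                 palindrome_eaf_window = palindrome_eaf_window,
                 se_mode = se_mode, boot_reps = boot_reps,
                 presso_nsim = presso_nsim, seed = as.integer(seed),
                 reverse = reverse),
            class = "mr_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [mr_config()].
#' @return An `mr_config` list.
#' @export
read_mr_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(mr_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(mr_config, vals)
}

stage_seed <- function(root, i, stage) {
  # deterministic per-stage stream; kept well inside 32-bit integer range
  (root + 7919L * i + stage) %% 2000000011L
}

analyse_pair <- function(exposure, outcome, instruments, proxies, config,
                         pair_index) {
  h <- harmonize(exposure, outcome, instruments, proxies,
                 config$palindrome_eaf_window)
  kept <- harmonized_kept(h)
  if (nrow(kept) < 3) {
    stop("fewer than 3 instruments survive harmonization", call. = FALSE)
  }
  ratios <- wald_ratios(kept, config$se_mode)
  ivw <- ivw_mre(ratios)
  sm <- simple_median(ratios, config$boot_reps,
                      stage_seed(config$seed, pair_index, 1L))
  wm <- weighted_median(ratios, config$boot_reps,
                        stage_seed(config$seed, pair_index, 2L))
  eg <- egger(kept)
  het <- cochran_q(ratios, ivw$beta)
  presso <- if (nrow(kept) >= 4) {
    withCallingHandlers(
      mr_presso(kept, config$presso_nsim,
                stage_seed(config$seed, pair_index, 3L)),
      warning = function(w) invokeRestart("muffleWarning"))
  } else NULL
  loo <- leave_one_out(kept, config$se_mode)
  list(outcome = attr(outcome, "trait_name"),
       harmonized = h,
       estimates = rbind(ivw, sm, wm, eg$slope, eg$intercept),
       heterogeneity = het, presso = presso, loo = loo,
       k = nrow(kept), error = NA_character_)
}

failed_pair <- function(outcome_name, err) {
  list(outcome = outcome_name, harmonized = NULL,
       estimates = mr_estimate("ivw_mre", NA_real_, NA_real_, NA_real_,
                               0L),
       heterogeneity = NULL, presso = NULL, loo = NULL, k = 0L,
       error = conditionMessage(err))
}

run_direction <- function(exposure, outcomes, ld, proxies, config,
                          index_offset) {
  cfg_clump <- clump_config(config$p_threshold, config$r2_threshold,
                            config$window_kb)
  instruments <- clump(exposure, ld, cfg_clump)
  results <- lapply(seq_along(outcomes), function(i) {
    tryCatch(
      analyse_pair(exposure, outcomes[[i]], instruments, proxies, config,
                   index_offset + i),
      error = function(e) {
        failed_pair(attr(outcomes[[i]], "trait_name"), e)
      })
  })
  names(results) <- vapply(results, `[[`, character(1), "outcome")
  # FDR family: the primary IVW p-values of this direction
  ivw_p <- vapply(results, function(r) r$estimates$pval[1], numeric(1))
  ok <- !is.na(ivw_p)
  qvals <- rep(NA_real_, length(ivw_p))
  qvals[ok] <- bh_fdr(ivw_p[ok])
  for (i in seq_along(results)) results[[i]]$qval <- qvals[i]
  list(instruments = instruments, results = results)
}

#' Run the full two-sample MR pipeline
#'
#' Orchestrates instrument selection, harmonization, the univariable
#' estimators, heterogeneity and pleiotropy diagnostics, leave-one-out
#' analysis, and Benjamini-Hochberg FDR correction of the primary IVW
#' p-values across outcomes; optionally repeats the analysis in the
#' reverse direction (each outcome as exposure). A fatal error in one
#' exposure-outcome pair aborts only that pair: it appears in the results
#' as an explicit NA row with the error message, and the run continues.
#' Every stochastic step is seeded deterministically from the
#' configuration seed, so identical inputs and configuration reproduce
#' identical outputs.
#'
#' @param exposure a `sumstats` object (or path read via
#'   [read_sumstats()]).
#' @param outcomes named list of `sumstats` objects (or paths).
#' @param ld an `ld_matrix` or `NULL`.
#' @param proxies a [proxy_map()] or `NULL`.
#' @param config an [mr_config()].
#' @return An `mr_pipeline` list: `forward` (per-outcome result lists with
#'   `estimates`, `heterogeneity`, `presso`, `loo`, `qval`), `reverse`
#'   (same shape or `NULL`), `forest` (tidy table from
#'   [forest_table()]), and `manifest` (config snapshot, package version,
#'   seed, per-stage row counts).
#' @export
run_pipeline <- function(exposure, outcomes, ld = NULL, proxies = NULL,
                         config = mr_config()) {
  if (is.character(exposure)) exposure <- read_sumstats(exposure)
  outcomes <- lapply(outcomes, function(o) {
    if (is.character(o)) read_sumstats(o) else o
  })
  forward <- run_direction(exposure, outcomes, ld, proxies, config, 0L)
  reverse <- NULL
  if (isTRUE(config$reverse)) {
    reverse <- lapply(seq_along(outcomes), function(i) {
      tryCatch({
        dir <- run_direction(outcomes[[i]], list(exposure), ld, proxies,
                             config, 1000L + i)
        dir$results[[1]]
      }, error = function(e) {
        failed_pair(attr(exposure, "trait_name"), e)
      })
    })
    names(reverse) <- names(outcomes)
  }
  forest <- forest_table(forward$results)
  manifest <- list(
    package = "summr",
    version = as.character(utils::packageVersion("summr")),
    config = unclass(config),
    exposure = attr(exposure, "trait_name"),
    n_instruments = length(forward$instruments),
    outcomes = vapply(forward$results, function(r) r$outcome, character(1)),
    k_per_outcome = vapply(forward$results, function(r) as.integer(r$k),
                           integer(1)),
    failed = vapply(forward$results,
                    function(r) !is.na(r$error), logical(1))
  )
  structure(list(forward = forward, reverse = reverse, forest = forest,
                 manifest = manifest),
            class = "mr_pipeline")
}

#' Forest-style results table
#'
#' Flattens per-outcome pipeline results into one row per outcome and
#' method, with odds ratios, confidence bounds, p-values and (for the
#' primary IVW rows) FDR q-values — the plain-text analogue of a forest
#' plot.
#'
#' @param results the `results` element of a pipeline direction.
#' @return Tibble with columns `outcome`, `method`, `k`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`, `or`, `or_low`, `or_high`, `qval`.
#' @export
forest_table <- function(results) {
  rows <- lapply(results, function(r) {
    est <- r$estimates
    est$outcome <- r$outcome
    est$qval <- ifelse(est$method == "ivw_mre", r$qval, NA_real_)
    est
  })
  out <- do.call(rbind, rows)
  out <- out[, c("outcome", "method", "k", "beta", "se", "ci_low",
                 "ci_high", "pval", "or", "or_low", "or_high", "qval")]
  rownames(out) <- NULL
  as_tibble(out)
}

#' Write a forest table to TSV
#'
#' @param forest tibble from [forest_table()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_forest_table <- function(forest, path) {
  out <- as.data.frame(forest)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.10g", x))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
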