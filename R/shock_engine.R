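# Monte Carlo shock engine: seeded draws of multiplicative wheat TFP shocks
# (i.i.d. normal around 1 with region-specific sigma_r, floored at 0.3 by
# clamping, not resampling) and the scenario batch runner collecting
# household wheat-consumption changes per draw.

#' Draw a Monte Carlo shock matrix
#'
#' Entry (k, r) is `max(floor, N(1, sigma_r))`; draws are independent across
#' draws and regions.  A region with `sigma_r = 0` (non-producer) has a
#' column identically 1.  The count of raw draws falling below the floor is
#' recorded per region.
#'
#' @param sigmas named per-region residual standard deviations (>= 0).
#' @param n_draws number of draws (default 1000).
#' @param floor minimum admissible multiplier (default 0.3).
#' @param seed integer seed.
#' @return a `shock_matrix`: `n_draws` x regions, with attributes `seed`,
#'   `sigmas`, `floor` and `truncated` (per-region clamp counts).
#' @export
draw_shocks <- function(sigmas, n_draws = 1000, floor = 0.3, seed = 1L) {
  if (any(sigmas < 0)) stopf("draw_shocks: sigmas must be >= 0")
  if (n_draws < 1) stopf("draw_shocks: n_draws must be >= 1")
  if (is.null(names(sigmas)))
    names(sigmas) <- paste0("REG", seq_along(sigmas))
  with_seed(seed, {
    raw <- matrix(stats::rnorm(n_draws * length(sigmas), mean = 1,
                               sd = rep(sigmas, each = n_draws)),
                  n_draws, length(sigmas),
                  dimnames = list(NULL, names(sigmas)))
    truncated <- as.integer(colSums(raw < floor))
    names(truncated) <- names(sigmas)
    structure(pmax(raw, floor),
              class = c("shock_matrix", "matrix", "array"),
              seed = as.integer(seed), sigmas = sigmas, floor = floor,
              truncated = truncated)
  })
}

#' Run a scenario batch over a shock matrix
#'
#' Solves the equilibrium once per draw and records each region's household
#' wheat (Armington composite) consumption as a percent change from the
#' benchmark reference year.  Under `Reference` no draws are run and all
#' changes are zero; under `YQ` the quota set is required and applied to
#' every draw.  The Y and YQ batches of a comparison must be run on the same
#' `shock_matrix` so their distributions are paired draw by draw.
#'
#' @param params a `cge_params`.
#' @param shocks a `shock_matrix` whose columns cover the model regions.
#' @param scenario one of `"Reference"`, `"Y"`, `"YQ"`.
#' @param quotas a `quota_set`; required iff `scenario == "YQ"`.
#' @param max_fail_frac abort when more than this fraction of solves fails
#'   (default 0.05); failed draws are excluded (set `NA`) and counted.
#' @param progress print a dot every 25 draws.
#' @return a `consumption_distribution`: draws x regions matrix of percent
#'   changes with attributes `scenario`, `seed`, `n_draws`, `failures`.
#' @export
run_batch <- function(params, shocks, scenario = c("Y", "YQ", "Reference"),
                      quotas = NULL, max_fail_frac = 0.05, progress = FALSE) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(params, "cge_params"))
  if (scenario == "YQ" && is.null(quotas))
    stopf("run_batch: scenario YQ requires a quota set")
  if (scenario != "YQ") quotas <- NULL
  regs <- params$regions
  if (!all(regs %in% colnames(shocks)))
    stopf("run_batch: shock matrix lacks columns for regions: %s",
          paste(setdiff(regs, colnames(shocks)), collapse = ", "))
  n <- nrow(shocks)
  out <- matrix(0, n, length(regs), dimnames = list(NULL, regs))
  failures <- 0L
  if (scenario != "Reference") {
    C0w <- params$C0[params$wheat_sector, ]
    for (k in seq_len(n)) {
      sh <- stats::setNames(as.numeric(shocks[k, regs]), regs)
      sol <- solve_equilibrium(params, shock = sh, quotas = quotas)
      if (inherits(sol, "cge_failure")) {
        out[k, ] <- NA_real_
        failures <- failures + 1L
      } else {
        out[k, ] <- 100 * (sol$C[params$wheat_sector, ] / C0w - 1)
      }
      if (progress && k %% 25 == 0) cat(".")
    }
    if (progress) cat("\n")
    if (failures > max_fail_frac * n)
      stopf("run_batch: %d of %d solves failed (> %.0f%%); distribution deemed unreliable",
            failures, n, 100 * max_fail_frac)
  }
  structure(out, class = c("consumption_distribution", "matrix", "array"),
            scenario = scenario, seed = attr(shocks, "seed"),
            n_draws = n, failures = failures)
}
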