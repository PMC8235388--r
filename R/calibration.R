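# Benchmark calibration: from a balanced SAM (plus elasticities) to the full
# parameter set of the nested CES/CET Armington model, under the unit-price
# benchmark convention.  Because quantities are stored in benchmark-value
# units, every share parameter is a benchmark value share and every scale
# parameter is absorbed into the units; `share_parameters()` exposes the share
# families for inspection and invariant checks.

#' Construct the elasticity set of the model
#'
#' @param sectors character vector of sector labels.
#' @param wheat_sector which sector is wheat (Armington default 4.45 there).
#' @param sigma_va per-sector factor-substitution elasticity in value added
#'   (placeholder default 1.2: the source database values are not public).
#' @param sigma_arm per-sector Armington elasticity (domestic vs. composite
#'   imports); wheat defaults to 4.45.
#' @param psi_cet per-sector transformation elasticity (domestic vs. aggregate
#'   exports); placeholder default 2.
#' @param sigma_imp per-sector elasticity among bilateral import sources
#'   (default twice the Armington elasticity, the usual two-nest convention).
#' @param psi_exp per-sector elasticity among bilateral export destinations
#'   (default equal to `psi_cet`).
#' @param food_elasticity household food-nest CES elasticity (default 0.1).
#' @return an object of class `elasticity_spec`.
#' @export
elasticity_spec <- function(sectors,
                            wheat_sector = sectors[1],
                            sigma_va = 1.2,
                            sigma_arm = ifelse(sectors == wheat_sector, 4.45, 2),
                            psi_cet = 2,
                            sigma_imp = 2 * sigma_arm,
                            psi_exp = psi_cet,
                            food_elasticity = 0.1) {
  S <- length(sectors)
  out <- list(sectors = as.character(sectors),
              wheat_sector = wheat_sector,
              sigma_va = stats::setNames(rep_len(sigma_va, S), sectors),
              sigma_arm = stats::setNames(rep_len(sigma_arm, S), sectors),
              psi_cet = stats::setNames(rep_len(psi_cet, S), sectors),
              sigma_imp = stats::setNames(rep_len(sigma_imp, S), sectors),
              psi_exp = stats::setNames(rep_len(psi_exp, S), sectors),
              food_elasticity = food_elasticity)
  vals <- unlist(out[c("sigma_va", "sigma_arm", "psi_cet", "sigma_imp",
                       "psi_exp", "food_elasticity")])
  if (any(vals <= 0)) stopf("elasticity_spec: all elasticities must be > 0")
  structure(out, class = "elasticity_spec")
}

#' Elasticity set implied by a world specification
#'
#' @param spec a [world_spec()].
#' @export
elasticities_from_spec <- function(spec) {
  elasticity_spec(spec$sectors, spec$wheat_sector,
                  sigma_va = spec$sigma_va, sigma_arm = spec$sigma_arm,
                  psi_cet = spec$psi_cet,
                  food_elasticity = spec$food_elasticity)
}

#' Calibrate the CGE parameter set from a benchmark SAM
#'
#' Reads the benchmark flows out of the SAM and stores them (in benchmark-value
#' units, so all benchmark prices are 1) together with the elasticities.
#' The resulting object satisfies the benchmark-replication property: the
#' equilibrium system built from it with unit shocks has zero residual at the
#' benchmark point.
#'
#' @param sam a balanced `sam_table` (from [generate_sam()] or
#'   [read_sam_csv()]).
#' @param elasticities an [elasticity_spec()]; defaults to the one implied by
#'   the spec attached to the SAM.
#' @param wheat_sector,food_sectors,mobile_factor structural labels; default
#'   to the generating spec attached to the SAM.
#' @return an object of class `cge_params`.
#' @export
calibrate <- function(sam, elasticities = NULL,
                      wheat_sector = NULL, food_sectors = NULL,
                      mobile_factor = NULL) {
  spec <- attr(sam, "spec")
  wheat_sector <- wheat_sector %||% spec$wheat_sector
  food_sectors <- food_sectors %||% spec$food_sectors
  mobile_factor <- mobile_factor %||% spec$mobile_factor
  if (is.null(wheat_sector) || is.null(food_sectors) || is.null(mobile_factor))
    stopf("calibrate: SAM carries no world_spec; supply wheat_sector, food_sectors and mobile_factor explicitly")

  accs <- rownames(sam)
  secacc <- grep("^sec:", accs, value = TRUE)
  parts <- do.call(rbind, strsplit(secacc, ":", fixed = TRUE))
  secs <- unique(parts[, 2]); regs <- unique(parts[, 3])
  facacc <- grep("^fac:", accs, value = TRUE)
  facs <- unique(do.call(rbind, strsplit(facacc, ":", fixed = TRUE))[, 2])
  S <- length(secs); R <- length(regs); Fk <- length(facs)
  specific <- setdiff(facs, mobile_factor)
  if (!mobile_factor %in% facs)
    stopf("calibrate: mobile factor '%s' has no factor accounts", mobile_factor)
  if (length(specific) < 1)
    stopf("calibrate: need at least one sector-specific factor")
  if (is.null(elasticities)) {
    elasticities <- if (!is.null(spec)) elasticities_from_spec(spec)
                    else elasticity_spec(secs, wheat_sector)
  }
  if (!setequal(elasticities$sectors, secs))
    stopf("calibrate: elasticity_spec sectors do not match the SAM")

  X0 <- array(0, c(S, S, R), dimnames = list(secs, secs, regs))
  F0 <- array(0, c(Fk, S, R), dimnames = list(facs, secs, regs))
  C0 <- matrix(0, S, R, dimnames = list(secs, regs))
  I0 <- matrix(0, S, R, dimnames = list(secs, regs))
  E0b <- array(0, c(S, R, R), dimnames = list(secs, regs, regs))
  Sav0 <- stats::setNames(numeric(R), regs)
  FS <- stats::setNames(numeric(R), regs)
  for (ri in seq_len(R)) {
    r <- regs[ri]
    X0[, , ri] <- sam[acc_sec(secs, r), acc_sec(secs, r)]
    F0[, , ri] <- sam[acc_fac(facs, r), acc_sec(secs, r)]
    C0[, ri] <- sam[acc_sec(secs, r), acc_hh(r)]
    I0[, ri] <- sam[acc_sec(secs, r), acc_inv(r)]
    Sav0[ri] <- sam[acc_inv(r), acc_hh(r)]
    FS[ri] <- (if (ACC_WLDSAV %in% accs) sam[acc_inv(r), ACC_WLDSAV] -
                 sam[ACC_WLDSAV, acc_inv(r)] else 0)
    for (si in seq_len(R)) {
      if (si == ri) next
      tr <- acc_trd(r, regs[si])
      if (tr %in% accs) E0b[, ri, si] <- sam[acc_sec(secs, r), tr]
    }
  }
  VA0 <- apply(F0, c(2, 3), sum)
  Z0 <- VA0 + apply(X0, c(2, 3), sum)
  E0agg <- apply(E0b, c(1, 2), sum)
  M0agg <- apply(E0b, c(1, 3), sum)
  D0 <- Z0 - E0agg
  Q0 <- D0 + M0agg

  zero_out <- which(Z0 <= 0 & (apply(X0, c(2, 3), sum) > 0), arr.ind = TRUE)
  if (nrow(zero_out) > 0)
    stopf("calibrate: sector '%s' in region '%s' has zero output but positive input flows",
          secs[zero_out[1, 1]], regs[zero_out[1, 2]])
  if (any(Z0 <= 0))
    stopf("calibrate: sector '%s' in region '%s' has non-positive gross output",
          secs[which(Z0 <= 0, arr.ind = TRUE)[1, 1]],
          regs[which(Z0 <= 0, arr.ind = TRUE)[1, 2]])
  if (any(F0 <= 0))
    stopf("calibrate: every sector must employ every factor (zero factor payment found)")
  if (any(D0 < -1e-9))
    stopf("calibrate: negative implied domestic sales (exports exceed output)")
  assert_balanced(sam)
  if (abs(sum(FS)) > 1e-6 * max(sam))
    stopf("calibrate: world foreign savings do not sum to zero")

  income0 <- colSums(VA0)
  Ctot0 <- colSums(C0)
  srate <- Sav0 / income0
  food <- intersect(secs, food_sectors)
  nonfood <- setdiff(secs, food)
  CF0 <- colSums(C0[food, , drop = FALSE])
  # Cobb-Douglas top level: value shares of the food composite and each
  # non-food good in total consumption spending
  muF <- CF0 / Ctot0
  mu <- sweep(C0, 2, Ctot0, "/"); mu[food, ] <- 0
  iota <- sweep(I0, 2, colSums(I0), "/")
  omega <- Q0 / sum(Q0)

  el <- elasticities
  expand <- function(v) matrix(v[secs], S, R, dimnames = list(secs, regs))
  structure(list(
    regions = regs, sectors = secs, factors = facs,
    mobile_factor = mobile_factor, specific_factors = specific,
    wheat_sector = wheat_sector, food_sectors = food, nonfood_sectors = nonfood,
    sigma_va = expand(el$sigma_va), sigma_arm = expand(el$sigma_arm),
    psi_cet = expand(el$psi_cet), sigma_imp = expand(el$sigma_imp),
    psi_exp = expand(el$psi_exp), sigma_food = el$food_elasticity,
    X0 = X0, F0 = F0, VA0 = VA0, Z0 = Z0, D0 = D0,
    E0b = E0b, E0agg = E0agg, M0agg = M0agg, Q0 = Q0,
    C0 = C0, I0 = I0, Sav0 = Sav0, FS = FS,
    Lbar = stats::setNames(colSums(matrix(F0[mobile_factor, , ], S, R)), regs),
    income0 = income0, srate = srate,
    muF = muF, mu = mu, iota = iota, omega = omega,
    reference_year = attr(sam, "reference_year") %||% 2014L
  ), class = "cge_params")
}

#' @export
print.cge_params <- function(x, ...) {
  cat("<cge_params> ", length(x$regions), " regions x ", length(x$sectors),
      " sectors x ", length(x$factors), " factors; wheat = '",
      x$wheat_sector, "'\n", sep = "")
  cat("  benchmark world gross output:", format(sum(x$Z0)), "\n")
  cat("  active bilateral flows:", sum(x$E0b > 0), "\n")
  invisible(x)
}

#' Share-parameter families of a calibrated model
#'
#' Returns every CES/CET/Cobb-Douglas share family as a list of vectors, each
#' nonnegative and summing to one -- the invariant checked by the calibration
#' tests.
#'
#' @param params a `cge_params`.
#' @export
share_parameters <- function(params) {
  p <- params
  fam <- list()
  for (r in seq_along(p$regions)) {
    rl <- p$regions[r]
    for (i in seq_along(p$sectors)) {
      il <- p$sectors[i]
      fam[[paste0("va:", il, ":", rl)]] <- p$F0[, i, r] / p$VA0[i, r]
      fam[[paste0("cet:", il, ":", rl)]] <-
        c(domestic = p$D0[i, r], exports = p$E0agg[i, r]) / p$Z0[i, r]
      fam[[paste0("armington:", il, ":", rl)]] <-
        c(domestic = p$D0[i, r], imports = p$M0agg[i, r]) / p$Q0[i, r]
      if (p$E0agg[i, r] > 0)
        fam[[paste0("export_dest:", il, ":", rl)]] <-
          p$E0b[i, r, ] / p$E0agg[i, r]
      if (p$M0agg[i, r] > 0)
        fam[[paste0("import_src:", il, ":", rl)]] <-
          p$E0b[i, , r] / p$M0agg[i, r]
    }
    fam[[paste0("cobb_douglas:", rl)]] <-
      c(food = p$muF[r], p$mu[p$nonfood_sectors, r])
    cf <- p$C0[p$food_sectors, r]
    fam[[paste0("food_nest:", rl)]] <- cf / sum(cf)
    fam[[paste0("investment:", rl)]] <- p$iota[, r]
  }
  fam
}

#' Size export-quota ceilings from baseline trade
#'
#' Ceilings are `fraction` times the baseline bilateral wheat export quantity
#' of each designated exporter (the default, reading the quota as a limit on
#' each bilateral flow), or `fraction` times the exporter's total baseline
#' wheat exports when `aggregate = TRUE`.
#'
#' @param params a `cge_params`.
#' @param exporters region labels imposing the quota.
#' @param fraction quota size as a fraction of baseline exports, in `(0, 1]`.
#' @param aggregate constrain each exporter's total wheat exports rather than
#'   each bilateral flow.
#' @return a `quota_set` data frame with columns sector, from, to (NA for
#'   aggregate quotas) and ceiling.
#' @export
quota_baseline <- function(params, exporters, fraction = 0.5,
                           aggregate = FALSE) {
  stopifnot(inherits(params, "cge_params"))
  if (!(fraction > 0 && fraction <= 1))
    stopf("quota_baseline: fraction must lie in (0, 1]")
  bad <- setdiff(exporters, params$regions)
  if (length(bad)) stopf("quota_baseline: unknown exporter '%s'", bad[1])
  w <- params$wheat_sector
  rows <- list()
  for (ex in exporters) {
    base <- params$E0b[w, ex, ]
    if (sum(base) <= 0)
      warnf("quota_baseline: exporter '%s' has zero baseline wheat exports; ceiling 0", ex)
    if (aggregate) {
      rows[[length(rows) + 1]] <- data.frame(
        sector = w, from = ex, to = NA_character_,
        ceiling = fraction * sum(base))
    } else {
      to <- names(base)[base > 0]
      if (length(to))
        rows[[length(rows) + 1]] <- data.frame(
          sector = w, from = ex, to = to,
          ceiling = fraction * base[to], row.names = NULL)
      else
        rows[[length(rows) + 1]] <- data.frame(
          sector = w, from = ex, to = NA_character_, ceiling = 0)
    }
  }
  structure(do.call(rbind, rows), class = c("quota_set", "data.frame"),
            fraction = fraction, aggregate = aggregate)
}

#' Serialize calibrated parameters to a structured text file
#'
#' Plain-text, `dget()`-compatible round trip for inspection and tests.
#'
#' @param params a `cge_params`.
#' @param path output file.
#' @export
write_params <- function(params, path) {
  x <- unclass(params)
  writeLines(deparse(x, control = c("keepInteger", "showAttributes",
                                    "niceNames", "keepNA", "hexNumeric")),
             path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  structure(dget(path), class = "cge_params")
}
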