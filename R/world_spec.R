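# World specification for the synthetic miniature economy.
#
# The synthetic world stands in for the proprietary multi-region database the
# real analysis is calibrated to: a configurable number of regions, a small
# sector list containing a designated wheat sector inside a food subset, and
# two production factors (one mobile across sectors, one sector-specific
# capital/land composite).  There is no government/tax block: the household
# owns all factors, saves at a fixed rate, and regional trade imbalances are
# absorbed by a fixed net-foreign-savings flow through a single world capital
# account.

#' Construct a world specification
#'
#' Defines the miniature multi-region economy from which a balanced social
#' accounting matrix (SAM) is generated.  All downstream stages (calibration,
#' equilibrium solving, Monte Carlo batches) are driven by the SAM this spec
#' produces, so the spec is the single place where the synthetic world's
#' structure is stated.
#'
#' @param regions character vector of region labels (at least 2).
#' @param sectors character vector of sector labels.
#' @param wheat_sector the sector carrying the productivity shock; must be a
#'   member of `food_sectors`.
#' @param food_sectors subset of `sectors` entering the household food nest.
#' @param factors character vector of factor labels (at least 2: one mobile
#'   factor and one or more sector-specific factors).
#' @param mobile_factor the factor that is mobile across sectors within a
#'   region (but not internationally).
#' @param sigma_va per-sector CES substitution elasticity between factors in
#'   value added (recycled to length `length(sectors)`).
#' @param sigma_arm per-sector Armington elasticity between domestic goods and
#'   the import composite; the wheat default is 4.45.
#' @param psi_cet per-sector elasticity of transformation between domestic
#'   sales and aggregate exports (default 2, a neutral mid-range placeholder).
#' @param food_elasticity CES elasticity of the household food nest
#'   (default 0.1).
#' @param export_share sectors x regions matrix (or scalar) of the share of
#'   gross output exported; must lie in `[0, 1)`.
#' @param import_dependence per-region nonnegative weights governing how
#'   attractive each region is as an export destination; a region with weight
#'   0 imports nothing.
#' @param savings_rate per-region household savings rate in `(0, 1)`.
#' @param symmetric if `TRUE`, all random structure is drawn once and copied
#'   across regions so that the world is exactly invariant under region
#'   relabelling (useful for symmetry oracles).
#' @param seed integer seed governing every random draw in the generators.
#' @return an object of class `world_spec`.
#' @export
world_spec <- function(regions = c("REG1", "REG2", "REG3"),
                       sectors = c("wheat", "ofood", "foodproc", "nonfood"),
                       wheat_sector = "wheat",
                       food_sectors = c("wheat", "ofood", "foodproc"),
                       factors = c("labor", "capital"),
                       mobile_factor = "labor",
                       sigma_va = 1.2,
                       sigma_arm = ifelse(sectors == wheat_sector, 4.45, 2),
                       psi_cet = 2,
                       food_elasticity = 0.1,
                       export_share = NULL,
                       import_dependence = rep(1, length(regions)),
                       savings_rate = rep(0.25, length(regions)),
                       symmetric = FALSE,
                       seed = 1L) {
  regions <- as.character(regions); sectors <- as.character(sectors)
  S <- length(sectors); R <- length(regions)
  if (R < 2) stopf("world_spec: need at least 2 regions, got %d", R)
  if (anyDuplicated(regions)) stopf("world_spec: duplicated region labels")
  if (anyDuplicated(sectors)) stopf("world_spec: duplicated sector labels")
  if (!wheat_sector %in% sectors)
    stopf("world_spec: wheat sector '%s' not among sectors", wheat_sector)
  if (!all(food_sectors %in% sectors))
    stopf("world_spec: food sectors must be a subset of sectors")
  if (!wheat_sector %in% food_sectors)
    stopf("world_spec: wheat sector must belong to the food subset")
  if (length(factors) < 2)
    stopf("world_spec: need a mobile and at least one specific factor")
  if (!mobile_factor %in% factors)
    stopf("world_spec: mobile factor '%s' not among factors", mobile_factor)

  if (is.null(export_share)) {
    export_share <- matrix(0.15, S, R, dimnames = list(sectors, regions))
    # one dominant wheat exporter, one import-dependent tail region
    export_share[wheat_sector, ] <- c(0.5, rep(0.08, R - 2), 0.02)
  } else if (length(export_share) == 1) {
    export_share <- matrix(export_share, S, R, dimnames = list(sectors, regions))
  } else {
    export_share <- matrix(export_share, S, R, dimnames = list(sectors, regions))
  }
  sigma_va <- rep_len(sigma_va, S); sigma_arm <- rep_len(sigma_arm, S)
  psi_cet <- rep_len(psi_cet, S)
  savings_rate <- rep_len(savings_rate, R)
  import_dependence <- rep_len(import_dependence, R)

  if (any(export_share < 0 | export_share >= 1))
    stopf("world_spec: export shares must lie in [0, 1)")
  if (any(c(sigma_va, sigma_arm, psi_cet, food_elasticity) <= 0))
    stopf("world_spec: all elasticities must be > 0")
  if (any(import_dependence < 0))
    stopf("world_spec: import dependence weights must be >= 0")
  if (any(savings_rate <= 0 | savings_rate >= 1))
    stopf("world_spec: savings rates must lie in (0, 1)")

  structure(list(
    regions = regions, sectors = sectors,
    wheat_sector = wheat_sector, food_sectors = as.character(food_sectors),
    factors = as.character(factors), mobile_factor = mobile_factor,
    sigma_va = stats::setNames(sigma_va, sectors),
    sigma_arm = stats::setNames(sigma_arm, sectors),
    psi_cet = stats::setNames(psi_cet, sectors),
    food_elasticity = food_elasticity,
    export_share = export_share,
    import_dependence = stats::setNames(import_dependence, regions),
    savings_rate = stats::setNames(savings_rate, regions),
    symmetric = isTRUE(symmetric),
    seed = as.integer(seed)
  ), class = "world_spec")
}

#' @export
print.world_spec <- function(x, ...) {
  cat("<world_spec> ", length(x$regions), " regions x ", length(x$sectors),
      " sectors x ", length(x$factors), " factors\n", sep = "")
  cat("  regions:", paste(x$regions, collapse = ", "), "\n")
  cat("  sectors:", paste(x$sectors, collapse = ", "),
      sprintf(" (wheat = %s)\n", x$wheat_sector))
  cat("  mobile factor:", x$mobile_factor, " seed:", x$seed, "\n")
  invisible(x)
}

#' Write / read a world specification as a flat plain-text file
#'
#' `key = value` lines (vectors comma-separated; the export-share matrix is
#' flattened sector-major), readable by [read_world_spec()] and by eye.
#'
#' @param spec a [world_spec()].
#' @param path file path.
#' @export
write_world_spec <- function(spec, path) {
  fmt <- function(v) paste(format(v, digits = 15, trim = TRUE), collapse = ",")
  lines <- c(
    paste("regions =", fmt(spec$regions)),
    paste("sectors =", fmt(spec$sectors)),
    paste("wheat_sector =", spec$wheat_sector),
    paste("food_sectors =", fmt(spec$food_sectors)),
    paste("factors =", fmt(spec$factors)),
    paste("mobile_factor =", spec$mobile_factor),
    paste("sigma_va =", fmt(spec$sigma_va)),
    paste("sigma_arm =", fmt(spec$sigma_arm)),
    paste("psi_cet =", fmt(spec$psi_cet)),
    paste("food_elasticity =", fmt(spec$food_elasticity)),
    paste("export_share =", fmt(as.vector(spec$export_share))),
    paste("import_dependence =", fmt(spec$import_dependence)),
    paste("savings_rate =", fmt(spec$savings_rate)),
    paste("symmetric =", if (spec$symmetric) "1" else "0"),
    paste("seed =", spec$seed))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_world_spec
#' @export
read_world_spec <- function(path) {
  cfg <- parse_config(path)
  world_spec(regions = cfg$regions, sectors = cfg$sectors,
             wheat_sector = cfg$wheat_sector,
             food_sectors = cfg$food_sectors,
             factors = cfg$factors, mobile_factor = cfg$mobile_factor,
             sigma_va = cfg$sigma_va, sigma_arm = cfg$sigma_arm,
             psi_cet = cfg$psi_cet, food_elasticity = cfg$food_elasticity,
             export_share = matrix(cfg$export_share, length(cfg$sectors),
                                   length(cfg$regions)),
             import_dependence = cfg$import_dependence,
             savings_rate = cfg$savings_rate,
             symmetric = cfg$symmetric == 1, seed = cfg$seed)
}

# account label helpers shared by the generator and the calibrator
acc_sec <- function(sector, region) paste0("sec:", sector, ":", region)
acc_fac <- function(factor, region) paste0("fac:", factor, ":", region)
acc_hh  <- function(region) paste0("hh:", region)
acc_inv <- function(region) paste0("inv:", region)
acc_trd <- function(from, to) paste0("trd:", from, ">", to)
ACC_WLDSAV <- "wldsav"
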