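# Nutrition-at-Risk accounting.
#
# Wheat supplies become nutrient supplies through per-kg nutrient contents;
# population requirements are built from an age-and-sex pyramid with
# recommended daily intakes (iron and zinc at a stated bioavailability tier,
# energy at moderate activity), a biomass adjustment on energy and protein,
# and a pregnancy increment proxied by the annual birth count.  The worst-tail
# consumption loss (value at risk, an order statistic of the Monte Carlo
# consumption distribution) times the wheat contribution share gives NAR: the
# loss expressed as a percentage of the population's annual requirement.

#' The six nutrients tracked by the pipeline
#' @export
NUTRIENTS <- c("protein", "energy", "iron", "zinc", "folate", "magnesium")

#' Generate internally consistent synthetic nutrition tables
#'
#' Produces a population pyramid (age band x sex), recommended daily intakes
#' per stratum, annual births, per-region annual wheat food supply, and a
#' per-region nutrient-per-kg wheat profile.  When `target_shares` is given
#' (regions x nutrients), the profile is back-solved so that the wheat
#' contribution share (annual wheat nutrient supply / annual population
#' requirement) equals the target exactly -- letting high-dependence regions
#' be emulated with known ground truth.
#'
#' @param regions region labels.
#' @param population named per-region population counts.
#' @param target_shares optional regions x nutrients matrix of contribution
#'   shares; defaults to moderate-dependence values around 0.2-0.7.
#' @param birth_rate births per person per year (default 0.012).
#' @param biomass_adjustment per-region multiplier on energy and protein
#'   requirements (default 1).
#' @param seed integer seed.
#' @return a `nutrition_tables` list with elements `pyramid`, `rni`,
#'   `pregnancy_increment`, `births`, `supply_kg`, `profile`,
#'   `biomass_adjustment`, `bioavailability`.
#' @export
generate_nutrition_tables <- function(regions,
                                      population = stats::setNames(
                                        rep(1e7, length(regions)), regions),
                                      target_shares = NULL,
                                      birth_rate = 0.012,
                                      biomass_adjustment = stats::setNames(
                                        rep(1, length(regions)), regions),
                                      seed = 1L) {
  regions <- as.character(regions)
  if (any(population < 0)) stopf("generate_nutrition_tables: negative population")
  with_seed(seed, {
    bands <- c("0-14", "15-29", "30-59", "60+")
    strata <- as.vector(outer(bands, c("F", "M"), paste, sep = "/"))
    # pyramid shape: common age structure with mild regional jitter
    base_sh <- c(0.25, 0.25, 0.35, 0.15) / 2
    pyr <- do.call(rbind, lapply(regions, function(r) {
      sh <- rep(base_sh, 2) * exp(stats::runif(8, -0.1, 0.1))
      sh <- sh / sum(sh)
      data.frame(region = r, stratum = strata,
                 count = round(population[r] * sh))
    }))
    # recommended daily intakes per stratum (synthetic but realistic scale):
    # protein g, energy kcal (moderate activity), iron mg (10% bioavail.),
    # zinc mg (moderate bioavail.), folate ug, magnesium mg
    rni <- data.frame(
      stratum = strata,
      protein = c(30, 46, 46, 46, 30, 56, 56, 56),
      energy = c(1800, 2100, 2000, 1800, 1900, 2600, 2500, 2100),
      iron = c(16, 29, 20, 11, 16, 14, 14, 14),
      zinc = c(6, 7, 7, 7, 6, 10, 10, 10),
      folate = c(300, 400, 400, 400, 300, 400, 400, 400),
      magnesium = c(180, 220, 220, 190, 180, 260, 260, 224))
    preg <- c(protein = 10, energy = 300, iron = 10, zinc = 3,
              folate = 200, magnesium = 40)
    births <- stats::setNames(round(birth_rate * population), regions)
    # annual wheat food supply: ~60 kg/person/year +- regional variation
    supply_kg <- stats::setNames(
      population * 60 * exp(stats::runif(length(regions), -0.4, 0.4)),
      regions)
    if (is.null(target_shares)) {
      target_shares <- matrix(stats::runif(length(regions) * length(NUTRIENTS),
                                           0.2, 0.7),
                              length(regions), length(NUTRIENTS),
                              dimnames = list(regions, NUTRIENTS))
    } else {
      target_shares <- as.matrix(target_shares)
      if (is.null(rownames(target_shares))) rownames(target_shares) <- regions
      if (is.null(colnames(target_shares))) colnames(target_shares) <- NUTRIENTS
    }
    tabs <- structure(list(
      pyramid = pyr, rni = rni, pregnancy_increment = preg, births = births,
      supply_kg = supply_kg, profile = NULL,
      biomass_adjustment = biomass_adjustment,
      bioavailability = c(iron = "10%", zinc = "moderate"),
      nutrients = NUTRIENTS
    ), class = "nutrition_tables")
    # back-solve the per-kg profile so contribution shares match the targets
    profile <- matrix(0, length(NUTRIENTS), length(regions),
                      dimnames = list(NUTRIENTS, regions))
    for (r in regions) {
      req <- population_requirement(
        pyr[pyr$region == r, ], rni, births[r],
        biomass_adjustment = biomass_adjustment[r],
        pregnancy_increment = preg)
      profile[, r] <- target_shares[r, NUTRIENTS] * req / supply_kg[r]
    }
    tabs$profile <- profile
    tabs
  })
}

#' Convert a wheat supply into nutrient supplies
#'
#' Elementwise product of an annual wheat food supply (kg) with a per-kg
#' nutrient profile.
#'
#' @param wheat_supply_kg annual wheat supply for human consumption, kg.
#' @param profile named per-kg nutrient contents covering [NUTRIENTS].
#' @return named per-nutrient annual supply.
#' @export
nutrient_supply <- function(wheat_supply_kg, profile) {
  if (wheat_supply_kg < 0) stopf("nutrient_supply: supply must be >= 0")
  miss <- setdiff(NUTRIENTS, names(profile))
  if (length(miss))
    stopf("nutrient_supply: profile lacks nutrient(s): %s",
          paste(miss, collapse = ", "))
  wheat_supply_kg * profile[NUTRIENTS]
}

#' Annual age- and sex-adjusted population nutrient requirement
#'
#' `sum(count * daily intake) * 365`, plus a pregnancy increment proxied by
#' the annual birth count, with energy and protein scaled by a regional
#' biomass adjustment.
#'
#' @param pyramid data frame with columns `stratum` and `count`.
#' @param rni_table data frame with column `stratum` and one column per
#'   nutrient: recommended daily intakes (iron/zinc at the configured
#'   bioavailability tier).
#' @param births annual number of births (proxy for pregnant women).
#' @param biomass_adjustment multiplier applied to energy and protein.
#' @param pregnancy_increment named per-nutrient daily increments for
#'   pregnancy.
#' @return named per-nutrient annual requirement.
#' @export
population_requirement <- function(pyramid, rni_table, births = 0,
                                   biomass_adjustment = 1,
                                   pregnancy_increment = NULL) {
  if (any(pyramid$count < 0)) stopf("population_requirement: negative counts")
  if (births < 0) stopf("population_requirement: negative births")
  if (sum(pyramid$count) + births == 0)
    stopf("population_requirement: zero population")
  nuts <- intersect(NUTRIENTS, names(rni_table))
  miss <- setdiff(pyramid$stratum, rni_table$stratum)
  if (length(miss))
    stopf("population_requirement: stratum '%s' has no intake values", miss[1])
  idx <- match(pyramid$stratum, rni_table$stratum)
  req <- vapply(nuts, function(n)
    sum(pyramid$count * rni_table[[n]][idx]) * 365, numeric(1))
  if (!is.null(pregnancy_increment) && births > 0) {
    pin <- pregnancy_increment[nuts]
    pin[is.na(pin)] <- 0
    req <- req + births * pin * 365
  }
  adj <- intersect(c("protein", "energy"), nuts)
  req[adj] <- req[adj] * biomass_adjustment
  req
}

#' Wheat contribution shares (supply over requirement)
#'
#' @param tables a `nutrition_tables`.
#' @return regions x nutrients matrix of dimensionless shares (may exceed 1).
#' @export
contribution_share <- function(tables) {
  stopifnot(inherits(tables, "nutrition_tables"))
  regs <- names(tables$supply_kg)
  out <- matrix(NA_real_, length(regs), length(NUTRIENTS),
                dimnames = list(regs, NUTRIENTS))
  for (r in regs) {
    sup <- nutrient_supply(tables$supply_kg[r],
                           stats::setNames(tables$profile[, r], NUTRIENTS))
    req <- population_requirement(
      tables$pyramid[tables$pyramid$region == r, ], tables$rni,
      tables$births[r], tables$biomass_adjustment[r],
      tables$pregnancy_increment)
    out[r, ] <- sup / req[NUTRIENTS]
  }
  out
}

#' Worst-tail value at risk of a consumption-change distribution
#'
#' The `ceiling(p * n)`-th smallest of the `n` values -- a pure order
#' statistic, no interpolation (for n = 1000, p = 0.05 this is the 50th
#' smallest value).
#'
#' @param dist numeric vector of consumption changes (NAs from failed solves
#'   are dropped), or a column of a `consumption_distribution`.
#' @param p tail probability in (0, 0.5).
#' @export
value_at_risk <- function(dist, p = 0.05) {
  dist <- as.numeric(dist)
  dist <- dist[!is.na(dist)]
  if (!length(dist)) stopf("value_at_risk: empty distribution")
  if (!(p > 0 && p < 0.5)) stopf("value_at_risk: p must lie in (0, 0.5)")
  sort(dist)[ceiling(p * length(dist))]
}

#' Nutrition at Risk from a VaR consumption change and contribution shares
#'
#' `NAR% = VaR% x share`, sign-preserving, one record per nutrient.
#'
#' @param var_value tail consumption change, percent of reference consumption.
#' @param share named per-nutrient contribution shares (or a single row of
#'   [contribution_share()]).
#' @param region,scenario,p labels carried into the result.
#' @return a `nar_result` data frame: region, nutrient, tail probability,
#'   VaR and NAR (percent of annual requirement).
#' @export
nar <- function(var_value, share, region = NA_character_,
                scenario = NA_character_, p = 0.05) {
  if (any(share < 0, na.rm = TRUE)) stopf("nar: shares must be >= 0")
  share <- if (is.matrix(share)) share[1, ] else share
  data.frame(region = region, nutrient = names(share),
             tail_probability = p, var_consumption_change = var_value,
             nar = var_value * as.numeric(share), scenario = scenario,
             row.names = NULL)
}

#' Return-period amplification between paired scenario distributions
#'
#' Locates the worst `p_ref` tail value of the yield-shock-only distribution
#' within the quota scenario's distribution: returns the empirical fraction of
#' the paired distribution at or below that value and its reciprocal as a
#' return period (1 draw = 1 year).
#'
#' @param dist_y,dist_yq paired per-region consumption-change vectors (columns
#'   of two `consumption_distribution`s run on the same shock matrix).
#' @param p_ref reference tail probability (default 0.01).
#' @return list with `var_y`, `probability`, `return_period_years`.
#' @export
return_period_amplification <- function(dist_y, dist_yq, p_ref = 0.01) {
  if (!(p_ref > 0 && p_ref < 0.5))
    stopf("return_period_amplification: p_ref must lie in (0, 0.5)")
  sy <- attr(dist_y, "pair_seed") %||% attr(dist_y, "seed")
  sq <- attr(dist_yq, "pair_seed") %||% attr(dist_yq, "seed")
  if (!is.null(sy) && !is.null(sq) && !identical(sy, sq))
    stopf("return_period_amplification: distributions are not paired (different shock seeds)")
  y <- as.numeric(dist_y); q <- as.numeric(dist_yq)
  y <- y[!is.na(y)]; q <- q[!is.na(q)]
  if (length(as.numeric(dist_y)) != length(as.numeric(dist_yq)))
    stopf("return_period_amplification: distributions are not paired (different draw counts)")
  v <- value_at_risk(y, p_ref)
  prob <- mean(q <= v)
  list(var_y = v, probability = prob,
       return_period_years = if (prob > 0) 1 / prob else Inf)
}

#' Assemble a wide NAR table across regions and nutrients
#'
#' One row per region, one column per nutrient (NAR as percent of annual
#' requirement), with losses above the reporting threshold flagged.
#'
#' @param dist a `consumption_distribution`.
#' @param shares regions x nutrients contribution-share matrix.
#' @param p tail probability (default 0.05).
#' @param flag_threshold absolute NAR percentage above which a loss is
#'   flagged (default 5).
#' @export
nar_table <- function(dist, shares, p = 0.05, flag_threshold = 5) {
  regs <- colnames(dist)
  rows <- lapply(regs, function(r) {
    v <- value_at_risk(dist[, r], p)
    nr <- v * shares[r, NUTRIENTS]
    df <- as.data.frame(as.list(nr))
    names(df) <- NUTRIENTS
    cbind(data.frame(region = r, var_consumption_change = v), df)
  })
  out <- do.call(rbind, rows)
  out$flagged <- apply(out[, NUTRIENTS], 1,
                       function(z) any(z < -flag_threshold))
  attr(out, "scenario") <- attr(dist, "scenario")
  attr(out, "tail_probability") <- p
  out
}
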