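# Static multi-region equilibrium core.
#
# Formulation (common world currency, calibrated share form, benchmark
# prices = 1):
#
#   * Leontief gross output over intermediate composites and a CES
#     value-added aggregate; the wheat productivity shifter alpha enters as a
#     Hicks-neutral multiplier on output per unit of the Leontief bundle.
#   * One mobile factor clears region-wide at a single wage; sector-specific
#     factors are fully employed, which pins sectoral value added given
#     relative factor prices (the first specific factor's market is inverted;
#     any additional specific factors contribute explicit clearing equations).
#   * CET between domestic sales and aggregate exports, then CET across
#     bilateral destinations; CES Armington between domestic goods and the
#     import composite, then CES across bilateral sources.
#   * Two-stage household demand: CES food nest (elasticity 0.1) under a
#     Cobb-Douglas top level; fixed savings rate (savings-driven closure);
#     investment allocated at fixed benchmark value shares; net foreign
#     savings fixed in numeraire (real) terms.
#   * Export quotas are imposed by an active-set scheme: a binding flow is
#     clamped to its ceiling and a producer price wedge (the quota rent,
#     accruing to the exporter's household) becomes an unknown.
#
# Unknowns (all strictly positive; the solver works on their logs): mobile
# wages, specific-factor prices, domestic goods prices, bilateral world
# prices, plus rent-wedge prices for clamped quotas.  Equations: zero profit,
# domestic goods clearing, mobile-factor clearing (one region's dropped by
# Walras' law), extra specific-factor clearing, bilateral flow clearing, and
# a numeraire equation fixing a world consumer-price index.  Every region's
# balance of payments is implied by its budget identities and serves as the
# Walras oracle via excess_demand().

.cd_eps <- 1e-6

# elementwise two-branch CES price index on matrices, with CD limit
.mix2_price <- function(pa, sa, pb, sb, sig) {
  cd <- abs(sig - 1) < .cd_eps
  ex <- ifelse(cd, 1, 1 - sig)
  out <- (sa * pa^ex + sb * pb^ex)^(1 / ex)
  if (any(cd)) {
    lg <- sa * log(pa) + sb * ifelse(sb > 0, log(pb), 0)
    out[cd] <- exp(lg[cd])
  }
  out
}

#' Build the equilibrium system for one shock draw
#'
#' Assembles the square nonlinear system (equal numbers of equations and
#' unknowns after numeraire normalization and Walras-redundancy removal) for
#' a calibrated world, a wheat TFP shock vector and an optional quota set.
#'
#' @param params a `cge_params` from [calibrate()].
#' @param shock named per-region multiplicative wheat TFP shifter (benchmark
#'   1); every entry must be >= 0.3, the computational floor.
#' @param quotas optional `quota_set` from [quota_baseline()].
#' @param numeraire target value of the benchmark-weighted world consumer
#'   price index (default 1).
#' @return an `equilibrium_system` with an equation/unknown census and a
#'   residual evaluator.
#' @export
build_system <- function(params, shock = NULL, quotas = NULL, numeraire = 1) {
  stopifnot(inherits(params, "cge_params"))
  p <- params
  S <- length(p$sectors); R <- length(p$regions)
  nspec <- length(p$specific_factors)
  shock <- shock %||% stats::setNames(rep(1, R), p$regions)
  if (is.null(names(shock))) names(shock) <- p$regions
  if (any(shock < 0.3 - 1e-12))
    stopf("build_system: shock below the 0.3 floor for region '%s'",
          names(shock)[which(shock < 0.3)[1]])
  alpha <- matrix(1, S, R, dimnames = dimnames(p$Z0))
  alpha[p$wheat_sector, names(shock)] <- shock

  flows <- which(p$E0b > 0)                       # linear index into S x R x R
  B <- length(flows)
  fidx <- arrayInd(flows, dim(p$E0b))
  flow_labels <- paste0(p$sectors[fidx[, 1]], ":", p$regions[fidx[, 2]],
                        ">", p$regions[fidx[, 3]])

  # resolve quota rows onto flow indices / exporter rows
  clamp_bil <- integer(0); clamp_bil_ceiling <- numeric(0)
  agg_rows <- integer(0); agg_ceiling <- numeric(0)   # linear index into S x R
  if (!is.null(quotas) && nrow(quotas) > 0) {
    for (k in seq_len(nrow(quotas))) {
      qs <- quotas[k, ]
      i <- match(qs$sector, p$sectors); r <- match(qs$from, p$regions)
      if (is.na(i) || is.na(r))
        stopf("build_system: quota names unknown sector/region ('%s'/'%s')",
              qs$sector, qs$from)
      if (is.na(qs$to)) {
        if (p$E0agg[i, r] > 0) {
          agg_rows <- c(agg_rows, i + (r - 1) * S)
          agg_ceiling <- c(agg_ceiling, qs$ceiling)
        }
      } else {
        s <- match(qs$to, p$regions)
        fl <- which(fidx[, 1] == i & fidx[, 2] == r & fidx[, 3] == s)
        if (length(fl)) {
          clamp_bil <- c(clamp_bil, fl)
          clamp_bil_ceiling <- c(clamp_bil_ceiling, qs$ceiling)
        }
      }
    }
  }

  # unknown layout (logs)
  n_wL <- R; n_wK <- nspec * S * R; n_pd <- S * R
  idx <- list(
    wL = seq_len(n_wL),
    wK = n_wL + seq_len(n_wK),
    pd = n_wL + n_wK + seq_len(n_pd),
    pw = n_wL + n_wK + n_pd + seq_len(B))
  n_base <- n_wL + n_wK + n_pd + B
  nc_b <- length(clamp_bil); nc_a <- length(agg_rows)
  idx$ptil <- if (nc_b) n_base + seq_len(nc_b) else integer(0)
  idx$ptilE <- if (nc_a) n_base + nc_b + seq_len(nc_a) else integer(0)
  n_unknowns <- n_base + nc_b + nc_a

  census_unknowns <- c(mobile_wage = n_wL, specific_factor_price = n_wK,
                       domestic_price = n_pd, bilateral_world_price = B,
                       quota_rent_price = nc_b + nc_a)
  census_equations <- c(zero_profit = S * R, domestic_clearing = S * R,
                        mobile_factor_clearing = R - 1,
                        extra_specific_clearing = (nspec - 1) * S * R,
                        bilateral_clearing = B,
                        quota_ceiling = nc_b + nc_a,
                        numeraire = 1)
  stopifnot(sum(census_unknowns) == sum(census_equations))

  # precomputed share / elasticity arrays --------------------------------
  facs <- p$factors; mob <- p$mobile_factor; spf <- p$specific_factors
  Fmob0 <- matrix(p$F0[mob, , ], S, R)
  Fsp0 <- array(p$F0[spf, , ], c(nspec, S, R))
  sF <- sweep(p$F0, c(2, 3), p$VA0, "/")
  sv <- p$sigma_va
  svF <- array(rep(sv, each = length(facs)), c(length(facs), S, R))
  cd_va <- abs(sv - 1) < .cd_eps
  shD_z <- p$D0 / p$Z0; shE_z <- p$E0agg / p$Z0
  shD_q <- p$D0 / p$Q0; shM_q <- p$M0agg / p$Q0
  shE <- array(0, dim(p$E0b))
  pos <- p$E0agg > 0
  shE_den <- array(rep(p$E0agg, times = R), dim(p$E0b))
  shE[p$E0b > 0] <- p$E0b[p$E0b > 0] / shE_den[p$E0b > 0]
  shMsrc <- array(0, dim(p$E0b))
  for (s in seq_len(R))
    shMsrc[, , s] <- sweep(matrix(p$E0b[, , s], S, R), 1,
                           pmax(p$M0agg[, s], 1e-300), "/")
  psi1 <- p$psi_cet; psi2 <- p$psi_exp
  sa <- p$sigma_arm; si <- p$sigma_imp
  food <- p$food_sectors; nonfood <- p$nonfood_sectors
  C0f <- p$C0[food, , drop = FALSE]
  CF0 <- colSums(C0f)
  sfood <- sweep(C0f, 2, CF0, "/")
  sfel <- p$sigma_food
  Kpay0 <- colSums(matrix(Fsp0, nspec * S, R))      # specific-factor income
  scale <- max(p$Z0)

  e_dom0 <- S * R                                   # residual offsets
  off_zp <- 0; off_dom <- S * R; off_lab <- 2 * S * R
  off_spec <- off_lab + (R - 1)
  off_bil <- off_spec + (nspec - 1) * S * R
  off_qc <- off_bil + B
  off_num <- off_qc + nc_b + nc_a
  n_eq <- off_num + 1

  agg_i <- ((agg_rows - 1) %% S) + 1
  agg_r <- ((agg_rows - 1) %/% S) + 1

  residual <- function(u, want_state = FALSE) {
    wL <- exp(u[idx$wL])
    wK <- array(exp(u[idx$wK]), c(nspec, S, R))
    pd <- matrix(exp(u[idx$pd]), S, R)
    pwv <- exp(u[idx$pw])
    ptil <- exp(u[idx$ptil])
    ptilE <- exp(u[idx$ptilE])

    # factor prices and value-added price index
    pf <- array(0, c(length(facs), S, R))
    pf[match(mob, facs), , ] <- rep(wL, each = S)
    pf[match(spf, facs), , ] <- wK
    A <- colSums(sF * pf^(1 - svF), dims = 1)
    py <- A^(1 / (1 - sv))
    if (any(cd_va)) {
      lg <- colSums(sF * log(pf), dims = 1)
      py[cd_va] <- exp(lg[cd_va])
    }
    wK1 <- matrix(wK[1, , ], S, R)
    Yrel <- (wK1 / py)^sv
    Ldem <- Fmob0 * Yrel * (py / rep(wL, each = S))^sv
    Zrel <- alpha * Yrel

    # export block
    pwm <- array(0, dim(p$E0b)); pwm[flows] <- pwv
    pep <- pwm
    if (nc_b) pep[flows[clamp_bil]] <- ptil
    psi2x <- array(rep(1 + psi2, times = R), dim(pep))
    pE2 <- matrix(1, S, R)
    if (B) {
      tmp <- shE * ifelse(pep > 0, pep, 1)^psi2x
      pE2[pos] <- (rowSums(tmp, dims = 2)[pos])^(1 / (1 + psi2[pos]))
    }
    pE_used <- pE2
    pEmkt <- NULL
    if (nc_a) {
      pE_used[agg_rows] <- ptilE
      tmpm <- shE * ifelse(pwm > 0, pwm, 1)^psi2x
      pEmkt <- (rowSums(tmpm, dims = 2))^(1 / (1 + psi2))
    }
    pz <- (shD_z * pd^(1 + psi1) + shE_z * pE_used^(1 + psi1))^(1 / (1 + psi1))
    Dsup <- p$D0 * Zrel * (pd / pz)^psi1
    Eagg <- p$E0agg * Zrel * (pE_used / pz)^psi1
    Erel <- matrix(0, S, R); Erel[pos] <- Eagg[pos] / p$E0agg[pos]
    alloc_p <- pep; alloc_idx <- pE2
    if (nc_a) {
      for (k in seq_along(agg_rows)) {
        alloc_p[agg_i[k], agg_r[k], ] <- pwm[agg_i[k], agg_r[k], ]
        alloc_idx[agg_rows[k]] <- pEmkt[agg_rows[k]]
      }
    }
    Eb <- array(0, dim(p$E0b))
    if (B) {
      ratio <- array(0, dim(p$E0b))
      ratio[flows] <- (alloc_p[flows] /
                         alloc_idx[fidx[, 1] + (fidx[, 2] - 1) * S])^
        (psi2[fidx[, 1] + (fidx[, 2] - 1) * S])
      Eb[flows] <- p$E0b[flows] * Erel[fidx[, 1] + (fidx[, 2] - 1) * S] *
        ratio[flows]
    }

    # import block
    pM <- matrix(1, S, R)
    hasM <- p$M0agg > 0
    if (B) {
      pMraw <- matrix(0, S, R)
      for (s in seq_len(R))
        pMraw[, s] <- rowSums(matrix(shMsrc[, , s], S, R) *
          ifelse(matrix(pwm[, , s], S, R) > 0,
                 matrix(pwm[, , s], S, R), 1)^rep(1 - si[, s], times = R))
      pM[hasM] <- pMraw[hasM]^(1 / (1 - si[hasM]))
    }
    pq <- .mix2_price(pd, shD_q, pM, shM_q, sa)
    Pnum <- sum(p$omega * pq)

    # household and investment
    rent <- stats::setNames(numeric(R), p$regions)
    if (nc_b) {
      fl <- flows[clamp_bil]
      r_of <- fidx[clamp_bil, 2]
      rr <- (pwm[fl] - ptil) * Eb[fl]
      for (k in seq_along(fl)) rent[r_of[k]] <- rent[r_of[k]] + rr[k]
    }
    if (nc_a) {
      for (k in seq_along(agg_rows))
        rent[agg_r[k]] <- rent[agg_r[k]] +
          (pEmkt[agg_rows[k]] - ptilE[k]) * Eagg[agg_rows[k]]
    }
    Kpay <- colSums(matrix(wK * Fsp0, nspec * S, R))
    income <- wL * p$Lbar + Kpay + rent
    Sav <- p$srate * income
    Cbud <- income - Sav
    ex_f <- if (abs(sfel - 1) < .cd_eps) 1 else 1 - sfel
    pqf <- pq[food, , drop = FALSE]
    pF <- (colSums(sfood * pqf^ex_f))^(1 / ex_f)
    QF <- p$muF * Cbud / pF
    C <- matrix(0, S, R, dimnames = dimnames(p$C0))
    C[food, ] <- C0f * rep(QF / CF0, each = length(food)) *
      (rep(pF, each = length(food)) / pqf)^sfel
    if (length(nonfood))
      C[nonfood, ] <- p$mu[nonfood, , drop = FALSE] *
        rep(Cbud, each = length(nonfood)) / pq[nonfood, , drop = FALSE]
    Ibud <- Sav + p$FS * Pnum
    Iq <- p$iota * rep(Ibud, each = S) / pq

    Qint <- matrix(0, S, R)
    for (r in seq_len(R)) Qint[, r] <- p$X0[, , r] %*% Yrel[, r]
    Qdem <- Qint + C + Iq
    Qrel <- Qdem / p$Q0
    cdm <- abs(sa - 1) < .cd_eps
    Ddem <- p$D0 * Qrel * ifelse(cdm, pq / pd, (pq / pd)^sa)
    Magg <- matrix(0, S, R)
    Magg[hasM] <- (p$M0agg * Qrel * ifelse(cdm, pq / pM, (pq / pM)^sa))[hasM]
    Mb <- array(0, dim(p$E0b))
    if (B) {
      Mrel <- matrix(0, S, R); Mrel[hasM] <- Magg[hasM] / p$M0agg[hasM]
      Mb[flows] <- p$E0b[flows] * Mrel[fidx[, 1] + (fidx[, 3] - 1) * S] *
        (pM[fidx[, 1] + (fidx[, 3] - 1) * S] / pwm[flows])^
        (si[fidx[, 1] + (fidx[, 3] - 1) * S])
    }

    # residual assembly
    res <- numeric(n_eq)
    costint <- matrix(0, S, R)
    for (r in seq_len(R)) costint[, r] <- crossprod(p$X0[, , r], pq[, r])
    res[off_zp + seq_len(S * R)] <-
      as.vector(pz * p$Z0 * alpha - (costint + py * p$VA0))
    res[off_dom + seq_len(S * R)] <- as.vector(Dsup - Ddem)
    labres <- colSums(Ldem) - p$Lbar
    res[off_lab + seq_len(R - 1)] <- labres[-1]
    if (nspec > 1) {
      ex <- array(0, c(nspec - 1, S, R))
      for (f in 2:nspec)
        ex[f - 1, , ] <- Fsp0[f, , ] *
          (Yrel * (py / matrix(wK[f, , ], S, R))^sv - 1)
      res[off_spec + seq_len((nspec - 1) * S * R)] <- as.vector(ex)
    }
    if (B) {
      bil <- Eb[flows] - Mb[flows]
      if (nc_b) bil[clamp_bil] <- Eb[flows[clamp_bil]] - clamp_bil_ceiling
      res[off_bil + seq_len(B)] <- bil
    }
    if (nc_b)
      res[off_qc + seq_len(nc_b)] <- Mb[flows[clamp_bil]] - clamp_bil_ceiling
    if (nc_a)
      res[off_qc + nc_b + seq_len(nc_a)] <- Eagg[agg_rows] - agg_ceiling
    res[off_num + 1] <- scale * (Pnum - numeraire)

    if (!want_state) return(res)
    dn2 <- dimnames(p$Z0); dn3 <- dimnames(p$E0b)
    for (nm in c("pd", "py", "pz", "pM", "pq", "Yrel", "Ldem", "Dsup",
                 "Ddem", "Eagg", "Magg", "Qdem")) {
      tmp <- get(nm); dimnames(tmp) <- dn2; assign(nm, tmp)
    }
    dimnames(pwm) <- dn3; dimnames(Eb) <- dn3; dimnames(Mb) <- dn3
    names(pF) <- p$regions
    list(res = res,
         state = list(
           wL = stats::setNames(wL, p$regions), wK = wK, pd = pd, pwm = pwm,
           ptil = ptil, ptilE = ptilE, py = py, pz = pz, pE = pE_used,
           pM = pM, pq = pq, pF = pF, Pnum = Pnum,
           Yrel = Yrel, Y = p$VA0 * Yrel, L = Ldem, Z = p$Z0 * Zrel,
           Dsup = Dsup, Ddem = Ddem, Eagg = Eagg, Eb = Eb, Magg = Magg,
           Mb = Mb, Qdem = Qdem, C = C, I = Iq, QF = QF,
           income = income, Sav = Sav, rent = rent, labres = labres))
  }

  structure(list(
    params = p, alpha = alpha, shock = shock, quotas = quotas,
    clamp_bil = clamp_bil, clamp_bil_ceiling = clamp_bil_ceiling,
    agg_rows = agg_rows, agg_ceiling = agg_ceiling,
    flows = flows, fidx = fidx, flow_labels = flow_labels,
    idx = idx, n_unknowns = n_unknowns, n_equations = n_eq,
    census_unknowns = census_unknowns, census_equations = census_equations,
    residual = residual, numeraire = numeraire, scale = scale
  ), class = "equilibrium_system")
}

#' @export
print.equilibrium_system <- function(x, ...) {
  cat("<equilibrium_system> ", length(x$params$regions), " regions x ",
      length(x$params$sectors), " sectors\n", sep = "")
  cat("Equation census:\n")
  for (nm in names(x$census_equations))
    cat(sprintf("  %-26s %4d\n", nm, x$census_equations[[nm]]))
  cat(sprintf("  %-26s %4d\n", "TOTAL", sum(x$census_equations)))
  cat("Unknown census:\n")
  for (nm in names(x$census_unknowns))
    cat(sprintf("  %-26s %4d\n", nm, x$census_unknowns[[nm]]))
  cat(sprintf("  %-26s %4d\n", "TOTAL", sum(x$census_unknowns)))
  invisible(x)
}

# damped Newton with numeric Jacobian on log unknowns
.newton <- function(resfun, u0, tol, max_iter = 40, h = 1e-7) {
  u <- u0
  r <- resfun(u)
  best <- max(abs(r))
  n <- length(u)
  iters <- 0
  while (iters < max_iter) {
    if (best < tol) break
    J <- matrix(0, length(r), n)
    for (j in seq_len(n)) {
      uj <- u; uj[j] <- uj[j] + h
      J[, j] <- (resfun(uj) - r) / h
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) return(list(u = u, res = r, norm = best,
                                   iterations = iters, converged = FALSE))
    lam <- 1
    ok <- FALSE
    for (k in 1:10) {
      ut <- u + lam * step
      rt <- tryCatch(resfun(ut), error = function(e) NULL)
      if (!is.null(rt) && all(is.finite(rt)) && max(abs(rt)) < best) {
        u <- ut; r <- rt; best <- max(abs(rt)); ok <- TRUE; break
      }
      lam <- lam / 2
    }
    iters <- iters + 1
    if (!ok) break
  }
  list(u = u, res = r, norm = best, iterations = iters, converged = best < tol)
}

# solve a fixed system (active set already chosen), with homotopy restarts
.solve_system <- function(system, u0 = NULL, tol = NULL, max_iter = 40) {
  tol <- tol %||% (1e-11 * system$scale)
  u0 <- u0 %||% numeric(system$n_unknowns)
  if (length(u0) != system$n_unknowns)
    u0 <- c(u0, numeric(system$n_unknowns - length(u0)))
  out <- .newton(system$residual, u0, tol, max_iter)
  if (!out$converged) {
    # homotopy in the shock: walk alpha from benchmark toward the target
    path <- c(0.25, 0.5, 0.75, 1)
    u <- numeric(system$n_unknowns)
    for (t in path) {
      sh <- 1 + t * (system$shock - 1)
      sys_t <- build_system(system$params, sh, system$quotas,
                            system$numeraire)
      st <- .newton(sys_t$residual, u, tol, max_iter)
      if (!st$converged && t < 1) next
      u <- st$u
      out <- st
    }
  }
  out
}

#' Solve the equilibrium system
#'
#' Damped Newton iteration on the logs of the strictly positive unknowns with
#' a benchmark warm start, homotopy-in-the-shock restarts, and (when quotas
#' are present) an outer active-set loop enforcing quota complementarity:
#' each quota either binds at its ceiling with nonnegative rent or is slack
#' with zero rent.
#'
#' @param system an `equilibrium_system`, or `cge_params` (with `shock` /
#'   `quotas` passed on).
#' @param shock,quotas used when `system` is a `cge_params`.
#' @param tol convergence tolerance on the residual infinity norm (value
#'   units; default `1e-9 * max(Z0)`).
#' @param warm_start optional initial log-price vector.
#' @return a `cge_solution`, or an object of class `cge_failure` carrying the
#'   best residual when the solver does not converge.
#' @export
solve_equilibrium <- function(system, shock = NULL, quotas = NULL, tol = NULL,
                              warm_start = NULL) {
  if (inherits(system, "cge_params"))
    system <- build_system(system, shock, quotas)
  stopifnot(inherits(system, "equilibrium_system"))
  p <- system$params
  tol <- tol %||% (1e-11 * system$scale)

  if (is.null(system$quotas) || nrow(system$quotas %||% data.frame()) == 0) {
    out <- .solve_system(system, warm_start, tol)
    return(.finish_solution(system, out, tol))
  }

  # active-set loop over binding quotas
  qs <- system$quotas
  active <- rep(FALSE, nrow(qs))
  u_prev <- NULL; base_n <- NULL
  out <- NULL
  for (pass in 1:12) {
    sys_k <- build_system(p, system$shock, qs[active, , drop = FALSE],
                          system$numeraire)
    u0 <- NULL
    if (!is.null(u_prev))
      u0 <- c(u_prev[seq_len(base_n)], numeric(sys_k$n_unknowns - base_n))
    out <- .solve_system(sys_k, u0, tol)
    if (!out$converged) break
    st <- sys_k$residual(out$u, want_state = TRUE)$state
    base_n <- length(sys_k$idx$wL) + length(sys_k$idx$wK) +
      length(sys_k$idx$pd) + length(sys_k$idx$pw)
    u_prev <- out$u

    # market-price export index, needed to price aggregate-quota rents
    psi2x <- array(rep(1 + p$psi_exp, times = length(p$regions)), dim(st$pwm))
    shE <- sweep(p$E0b, c(1, 2), pmax(p$E0agg, 1e-300), "/")
    pEmkt <- (rowSums(shE * ifelse(st$pwm > 0, st$pwm, 1)^psi2x,
                      dims = 2))^(1 / (1 + p$psi_exp))

    changed <- FALSE
    nb <- 0; na_ <- 0     # counters into ptil / ptilE (build order = row order)
    for (k in seq_len(nrow(qs))) {
      i <- match(qs$sector[k], p$sectors); r <- match(qs$from[k], p$regions)
      if (is.na(qs$to[k])) {
        if (p$E0agg[i, r] <= 0) next
        if (active[k]) {
          na_ <- na_ + 1
          if (pEmkt[i, r] - st$ptilE[na_] < -1e-9) {
            active[k] <- FALSE; changed <- TRUE
          }
        } else if (st$Eagg[i, r] > qs$ceiling[k] * (1 + 1e-9)) {
          active[k] <- TRUE; changed <- TRUE
        }
      } else {
        s <- match(qs$to[k], p$regions)
        if (p$E0b[i, r, s] <= 0) next
        if (active[k]) {
          nb <- nb + 1
          if (st$pwm[i, r, s] - st$ptil[nb] < -1e-9) {
            active[k] <- FALSE; changed <- TRUE
          }
        } else if (st$Eb[i, r, s] > qs$ceiling[k] * (1 + 1e-9)) {
          active[k] <- TRUE; changed <- TRUE
        }
      }
    }
    if (!changed) return(.finish_solution(sys_k, out, tol))
  }
  if (!is.null(out) && !out$converged)
    return(structure(list(norm = out$norm, iterations = out$iterations,
                          message = "solver failed to converge"),
                     class = "cge_failure"))
  structure(list(message = "quota active set failed to settle"),
            class = "cge_failure")
}

.finish_solution <- function(system, out, tol) {
  if (!out$converged)
    return(structure(list(norm = out$norm, iterations = out$iterations,
                          message = "solver failed to converge"),
                     class = "cge_failure"))
  st <- system$residual(out$u, want_state = TRUE)$state
  p <- system$params
  # quota rents per clamped flow
  quota_info <- NULL
  if (length(system$clamp_bil) || length(system$agg_rows)) {
    rows <- list()
    if (length(system$clamp_bil)) {
      fi <- system$fidx[system$clamp_bil, , drop = FALSE]
      fl <- system$flows[system$clamp_bil]
      rows[[1]] <- data.frame(
        sector = p$sectors[fi[, 1]], from = p$regions[fi[, 2]],
        to = p$regions[fi[, 3]], ceiling = system$clamp_bil_ceiling,
        exports = st$Eb[fl], rent_per_unit = st$pwm[fl] - st$ptil)
    }
    if (length(system$agg_rows)) {
      ai <- ((system$agg_rows - 1) %% length(p$sectors)) + 1
      ar <- ((system$agg_rows - 1) %/% length(p$sectors)) + 1
      tmpm <- st$pwm
      shE <- sweep(p$E0b, c(1, 2), pmax(p$E0agg, 1e-300), "/")
      pEmkt <- apply(shE * ifelse(tmpm > 0, tmpm, 1)^
                       array(rep(1 + p$psi_exp, times = length(p$regions)),
                             dim(tmpm)), c(1, 2), sum)^(1 / (1 + p$psi_exp))
      rows[[length(rows) + 1]] <- data.frame(
        sector = p$sectors[ai], from = p$regions[ar], to = NA_character_,
        ceiling = system$agg_ceiling, exports = st$Eagg[system$agg_rows],
        rent_per_unit = pEmkt[system$agg_rows] - st$ptilE)
    }
    quota_info <- do.call(rbind, rows)
  }
  structure(c(st, list(
    params = p, alpha = system$alpha, shock = system$shock,
    u = out$u, quota_info = quota_info,
    diagnostics = list(iterations = out$iterations, max_residual = out$norm,
                       tol = tol, n_unknowns = system$n_unknowns)
  )), class = "cge_solution")
}

#' @export
print.cge_solution <- function(x, ...) {
  cat("<cge_solution> converged in", x$diagnostics$iterations,
      "Newton steps; max residual", format(x$diagnostics$max_residual), "\n")
  cat("  consumer price index:", format(x$Pnum), "\n")
  if (!is.null(x$quota_info)) {
    cat("  binding quotas:\n"); print(x$quota_info)
  }
  invisible(x)
}

#' Dump an equilibrium solution to long-format CSV
#'
#' One row per variable: region, block, name, value; prices and quantities of
#' every block, plus solver diagnostics in a trailing comment line.
#'
#' @param solution a `cge_solution`.
#' @param path file path.
#' @export
solution_to_csv <- function(solution, path) {
  stopifnot(inherits(solution, "cge_solution"))
  p <- solution$params
  rows <- list()
  add <- function(block, name, region, value)
    rows[[length(rows) + 1]] <<- data.frame(region = region, block = block,
                                            name = name, value = value)
  add("factor_price", "mobile_wage", p$regions, as.numeric(solution$wL))
  for (mat in c("pd", "py", "pz", "pq", "pM")) {
    m <- solution[[mat]]
    for (r in p$regions) add("price", paste0(mat, ":", rownames(m)), r, m[, r])
  }
  for (mat in c("Z", "Y", "Dsup", "Eagg", "Magg", "Qdem", "C", "I")) {
    m <- solution[[mat]]
    for (r in p$regions)
      add("quantity", paste0(mat, ":", rownames(m)), r, m[, r])
  }
  fl <- which(solution$Eb > 0)
  if (length(fl)) {
    fi <- arrayInd(fl, dim(solution$Eb))
    add("bilateral", paste0("E:", p$sectors[fi[, 1]], ">",
                            p$regions[fi[, 3]]),
        p$regions[fi[, 2]], solution$Eb[fl])
  }
  add("household", "income", p$regions, as.numeric(solution$income))
  add("household", "savings", p$regions, as.numeric(solution$Sav))
  add("household", "quota_rent", p$regions, as.numeric(solution$rent))
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wheatnar solution; iterations=%d; max_residual=%g",
                     solution$diagnostics$iterations,
                     solution$diagnostics$max_residual), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Signed excess demand for a named market
#'
#' Evaluates demand minus supply for one market of a solved system, including
#' the markets omitted from the solved square system: the Walras-dropped
#' mobile-factor market of the first region and every region's balance of
#' payments (implied by budget closure), which serve as solver-correctness
#' oracles.
#'
#' @param solution a `cge_solution`.
#' @param market one of `"labor:<region>"`, `"good:<sector>:<region>"`
#'   (domestic goods market), `"bilateral:<sector>:<from>:<to>"`,
#'   `"bop:<region>"` (balance of payments, world currency), `"numeraire"`,
#'   or `"walras"` (alias for the dropped labor market).
#' @return the signed gap (demand minus supply).
#' @export
excess_demand <- function(solution, market) {
  stopifnot(inherits(solution, "cge_solution"))
  p <- solution$params
  if (market == "walras") market <- paste0("labor:", p$regions[1])
  parts <- strsplit(market, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  if (kind == "numeraire") return(solution$Pnum - 1)
  if (kind == "labor") {
    r <- match(parts[2], p$regions)
    if (is.na(r)) stopf("excess_demand: unknown region '%s'", parts[2])
    return(solution$labres[r])
  }
  if (kind == "good") {
    i <- match(parts[2], p$sectors); r <- match(parts[3], p$regions)
    if (is.na(i) || is.na(r)) stopf("excess_demand: unknown market '%s'", market)
    return(solution$Ddem[i, r] - solution$Dsup[i, r])
  }
  if (kind == "bilateral") {
    i <- match(parts[2], p$sectors); from <- match(parts[3], p$regions)
    to <- match(parts[4], p$regions)
    if (anyNA(c(i, from, to))) stopf("excess_demand: unknown market '%s'", market)
    return(solution$Mb[i, from, to] - solution$Eb[i, from, to])
  }
  if (kind == "bop") {
    r <- match(parts[2], p$regions)
    if (is.na(r)) stopf("excess_demand: unknown region '%s'", parts[2])
    exports <- sum(solution$pwm[, r, ] * solution$Eb[, r, ])
    imports <- sum(solution$pwm[, , r] * solution$Mb[, , r])
    return(imports - exports - p$FS[r] * solution$Pnum)
  }
  stopf("excess_demand: unknown market '%s'", market)
}
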