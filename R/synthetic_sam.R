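# Synthetic balanced SAM generator.
#
# The SAM is assembled from a constructed benchmark equilibrium at unit
# prices: gross outputs, input coefficients, factor splits and bilateral trade
# flows are drawn first, then household consumption and investment absorb the
# remaining domestic supply so that zero profit, market clearing and budget
# balance hold exactly by construction.  Accounts are, per region: one account
# per sector (activity and commodity merged), one per factor, a household, a
# savings-investment account; plus one bilateral trade account per ordered
# region pair and a single world capital account closing net foreign savings.

#' Generate a balanced synthetic social accounting matrix
#'
#' @param spec a [world_spec()].
#' @return a square numeric matrix of class `sam_table` with account labels on
#'   both dimensions, one reference year, and the generating spec attached as
#'   an attribute.  Row sums equal column sums to machine precision.
#' @export
generate_sam <- function(spec) {
  stopifnot(inherits(spec, "world_spec"))
  regs <- spec$regions; secs <- spec$sectors; facs <- spec$factors
  R <- length(regs); S <- length(secs); Fk <- length(facs)
  mob <- spec$mobile_factor
  specific <- setdiff(facs, mob)

  with_seed(spec$seed, {
    draw_structure <- function() {
      list(
        scale = 100 * exp(stats::runif(1, -0.35, 0.35)),
        zmix  = exp(stats::runif(S, -0.25, 0.25)),
        axraw = matrix(stats::runif(S * S, 0.2, 1), S, S),
        axtot = stats::runif(S, 0.25, 0.4),
        labsh = stats::runif(S, 0.35, 0.65),
        spmix = matrix(stats::runif(length(specific) * S, 0.5, 1),
                       length(specific), S)
      )
    }
    draws <- vector("list", R)
    if (spec$symmetric) {
      d1 <- draw_structure()
      for (r in seq_len(R)) draws[[r]] <- d1
    } else {
      for (r in seq_len(R)) draws[[r]] <- draw_structure()
    }

    sector_base <- c(0.6, 0.8, 1, 1.4)[((seq_len(S) - 1) %% 4) + 1]

    Z0 <- matrix(0, S, R, dimnames = list(secs, regs))
    X0 <- array(0, c(S, S, R), dimnames = list(secs, secs, regs))
    F0 <- array(0, c(Fk, S, R), dimnames = list(facs, secs, regs))
    wheat_i <- match(spec$wheat_sector, secs)
    for (r in seq_len(R)) {
      d <- draws[[r]]
      Z0[, r] <- sector_base * d$zmix * d$scale
      # wheat feeds intermediate use lightly (mainly food processing), which
      # also keeps heavily exporting wheat sectors feasible
      d$axraw[wheat_i, ] <- 0.2 * d$axraw[wheat_i, ]
      ax <- sweep(d$axraw, 2, colSums(d$axraw), "/")   # column-stochastic
      ax <- sweep(ax, 2, d$axtot, "*")                 # column sums = axtot
      X0[, , r] <- sweep(ax, 2, Z0[, r], "*")
      va <- (1 - d$axtot) * Z0[, r]
      F0[mob, , r] <- d$labsh * va
      spl <- sweep(d$spmix, 2, colSums(d$spmix), "/")
      F0[specific, , r] <- sweep(spl, 2, (1 - d$labsh) * va, "*")
    }
    VA0 <- apply(F0, c(2, 3), sum)

    # bilateral exports: destination weights from import dependence x size
    Etot <- spec$export_share * Z0
    size <- vapply(draws, function(d) d$scale, numeric(1))
    wdest <- spec$import_dependence * size
    E0b <- array(0, c(S, R, R), dimnames = list(secs, regs, regs))
    for (r in seq_len(R)) {
      w <- wdest; w[r] <- 0
      if (sum(w) > 0) {
        w <- w / sum(w)
        for (s in seq_len(R)) E0b[, r, s] <- Etot[, r] * w[s]
      } else if (any(Etot[, r] > 0)) {
        stopf("generate_sam: region %s exports but no destination has positive import dependence",
              regs[r])
      }
    }
    M0 <- apply(E0b, c(1, 3), sum)          # imports of sector i into region s
    D0 <- Z0 - Etot
    Q0 <- D0 + M0

    Xuse <- apply(X0, c(1, 3), sum)          # intermediate use of good i in r
    AV <- Q0 - Xuse                          # left for final absorption
    bad <- which(AV <= 1e-9, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stopf("generate_sam: infeasible spec -- domestic absorption of sector '%s' in region '%s' is non-positive (trade shares too high?)",
            secs[bad[1, 1]], regs[bad[1, 2]])

    income <- colSums(VA0)
    Sav <- spec$savings_rate * income
    FS <- colSums(M0) - colSums(Etot)        # net foreign savings inflow
    Itot <- Sav + FS
    Ctot <- income - Sav
    if (any(Itot <= 0))
      stopf("generate_sam: infeasible spec -- non-positive investment in region '%s' (savings rate too low for its trade surplus)",
            regs[which(Itot <= 0)[1]])
    C0 <- sweep(AV, 2, Ctot / (Ctot + Itot), "*")
    I0 <- AV - C0

    # ---- assemble the matrix -------------------------------------------
    accounts <- c(
      unlist(lapply(regs, function(r) c(
        acc_sec(secs, r), acc_fac(facs, r), acc_hh(r), acc_inv(r)))),
      unlist(lapply(regs, function(r)
        acc_trd(r, setdiff(regs, r)))),
      ACC_WLDSAV
    )
    sam <- matrix(0, length(accounts), length(accounts),
                  dimnames = list(accounts, accounts))
    for (ri in seq_len(R)) {
      r <- regs[ri]
      sam[acc_sec(secs, r), acc_sec(secs, r)] <- X0[, , ri]
      sam[acc_fac(facs, r), acc_sec(secs, r)] <- F0[, , ri]
      sam[acc_hh(r), acc_fac(facs, r)] <- rowSums(F0[, , ri, drop = FALSE])
      sam[acc_sec(secs, r), acc_hh(r)] <- C0[, ri]
      sam[acc_inv(r), acc_hh(r)] <- Sav[ri]
      sam[acc_sec(secs, r), acc_inv(r)] <- I0[, ri]
      if (FS[ri] >= 0) sam[acc_inv(r), ACC_WLDSAV] <- FS[ri]
      else sam[ACC_WLDSAV, acc_inv(r)] <- -FS[ri]
      for (si in seq_len(R)) {
        if (si == ri) next
        s <- regs[si]
        sam[acc_sec(secs, r), acc_trd(r, s)] <- E0b[, ri, si]
        sam[acc_trd(r, s), acc_sec(secs, s)] <- E0b[, ri, si]
      }
    }
    structure(sam,
              class = c("sam_table", "matrix", "array"),
              spec = spec, reference_year = 2014L)
  })
}

#' Check SAM balance
#'
#' @param sam a `sam_table` (or any square named matrix of money flows).
#' @param tol relative tolerance on `|rowsum - colsum| / max(entry)`.
#' @return `TRUE` invisibly; errors with the worst offending account otherwise.
#' @export
assert_balanced <- function(sam, tol = 1e-8) {
  gap <- abs(rowSums(sam) - colSums(sam))
  rel <- gap / max(sam, 1e-12)
  if (any(rel > tol)) {
    i <- which.max(rel)
    stopf("SAM unbalanced: account '%s' row-col gap %.3e (relative %.3e)",
          rownames(sam)[i], gap[i], rel[i])
  }
  invisible(TRUE)
}

#' Write / read a SAM as long-format CSV
#'
#' The on-disk format is `account_row, account_col, value` with zero cells
#' omitted; account order is preserved through an attribute-free round trip by
#' listing every account at least once (diagonal zeros are written for
#' otherwise empty accounts).
#'
#' @param sam a `sam_table`.
#' @param path file path.
#' @export
write_sam_csv <- function(sam, path) {
  idx <- which(sam != 0, arr.ind = TRUE)
  df <- data.frame(account_row = rownames(sam)[idx[, 1]],
                   account_col = colnames(sam)[idx[, 2]],
                   value = sam[idx])
  seen <- union(df$account_row, df$account_col)
  miss <- setdiff(rownames(sam), seen)
  if (length(miss))
    df <- rbind(df, data.frame(account_row = miss, account_col = miss,
                               value = 0))
  ord <- order(match(df$account_row, rownames(sam)),
               match(df$account_col, colnames(sam)))
  utils::write.csv(df[ord, ], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sam_csv
#' @param account_order optional explicit account ordering for the matrix.
#' @export
read_sam_csv <- function(path, account_order = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  accs <- account_order %||% unique(c(df$account_row, df$account_col))
  sam <- matrix(0, length(accs), length(accs), dimnames = list(accs, accs))
  sam[cbind(match(df$account_row, accs), match(df$account_col, accs))] <- df$value
  structure(sam, class = c("sam_table", "matrix", "array"))
}
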