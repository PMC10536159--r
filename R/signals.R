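# Disproportionality statistics on the 2x2 reporting contingency table
#
#              target event   other events
#   target drug      a             c
#   other drugs      b             d
#
# All four estimators are simple functions of (a,b,c,d); they are
# vectorized over tables so a whole screen is computed in one call.
#
#   ROR  = ad/(bc),                 95% CI exp(ln ROR +- 1.96*sqrt(1/a+1/b+1/c+1/d))
#   PRR  = (a/(a+b)) / (c/(c+d)),   95% CI exp(ln PRR +- 1.96*sqrt(1/a-1/(a+b)+1/c-1/(c+d)))
#   IC   = log2(aN/((a+b)(a+c))),   IC-2SD = IC - 2*sqrt(V(IC))
#   EBGM = aN/((a+c)(a+b)),         EBGM05 = exp(ln EBGM - 1.96*sqrt(1/a+1/b+1/c+1/d))
#
# IC and EBGM share the observed/expected closed form, so IC == log2(EBGM)
# holds exactly for every table.

.z95 <- 1.96

# coerce to double (avoiding integer overflow in products) and recycle
# scalars to the longest cell vector
.recycle_cells <- function(a, b, c, d, env = parent.frame()) {
  len <- max(length(a), length(b), length(c), length(d))
  if (any(!(c(length(a), length(b), length(c), length(d)) %in% c(1L, len)))) {
    stop("a, b, c, d must have length 1 or a common length", call. = FALSE)
  }
  assign("a", rep_len(as.numeric(a), len), envir = env)
  assign("b", rep_len(as.numeric(b), len), envir = env)
  assign("c", rep_len(as.numeric(c), len), envir = env)
  assign("d", rep_len(as.numeric(d), len), envir = env)
  invisible(len)
}

.check_cells <- function(a, b, c, d) {
  !is.na(a) & !is.na(b) & !is.na(c) & !is.na(d) &
    a > 0 & b > 0 & c > 0 & d > 0
}

#' Reporting odds ratio with Wald 95% interval
#'
#' @param a,b,c,d cells of the 2x2 table(s): `a` target drug with the
#'   event, `b` other drugs with the event, `c` target drug with other
#'   events, `d` other drugs with other events. Vectorized.
#' @return data.table with columns `ror`, `ror_lo`, `ror_hi`. Rows with a
#'   non-positive cell are `NA` (apply a zero-cell policy first, see
#'   [signal_stats()]).
#' @examples
#' ror_stat(3, 7, 97, 9893)
#' @export
ror_stat <- function(a, b, c, d) {
  .recycle_cells(a, b, c, d)
  ok <- .check_cells(a, b, c, d)
  est <- se <- rep(NA_real_, length(a))
  est[ok] <- (a[ok] * d[ok]) / (b[ok] * c[ok])
  se[ok] <- sqrt(1 / a[ok] + 1 / b[ok] + 1 / c[ok] + 1 / d[ok])
  data.table(ror = est, ror_lo = exp(log(est) - .z95 * se),
             ror_hi = exp(log(est) + .z95 * se))
}

#' Proportional reporting ratio with Wald 95% interval
#'
#' @inheritParams ror_stat
#' @return data.table with columns `prr`, `prr_lo`, `prr_hi`.
#' @export
prr_stat <- function(a, b, c, d) {
  .recycle_cells(a, b, c, d)
  ok <- .check_cells(a, b, c, d)
  est <- se <- rep(NA_real_, length(a))
  est[ok] <- (a[ok] / (a[ok] + b[ok])) / (c[ok] / (c[ok] + d[ok]))
  se[ok] <- sqrt(1 / a[ok] - 1 / (a[ok] + b[ok]) + 1 / c[ok] - 1 / (c[ok] + d[ok]))
  data.table(prr = est, prr_lo = exp(log(est) - .z95 * se),
             prr_hi = exp(log(est) + .z95 * se))
}

#' Pearson chi-square for a 2x2 table
#'
#' Closed form `N(|ad-bc| - yates*N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, with the
#' Yates continuity correction on by default (the MHRA convention pairing
#' PRR with a corrected chi-square). The corrected |ad-bc| is floored at 0.
#' Degenerate margins give `NA`.
#'
#' @inheritParams ror_stat
#' @param yates apply the continuity correction (default `TRUE`).
#' @return numeric vector of chi-square statistics.
#' @export
chi_square <- function(a, b, c, d, yates = TRUE) {
  .recycle_cells(a, b, c, d)
  n <- a + b + c + d
  m1 <- (a + b) * (c + d) * (a + c) * (b + d)
  out <- rep(NA_real_, length(a))
  ok <- !is.na(m1) & m1 > 0
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(dev - n / 2, 0)
  out[ok] <- n[ok] * dev[ok]^2 / m1[ok]
  out
}

#' BCPNN information component
#'
#' `IC = log2(aN / ((a+b)(a+c)))`, the log2 observed/expected reporting
#' ratio. The lower uncertainty bound `IC-2SD = IC - 2*sqrt(V(IC))` uses by
#' default the delta-method variance
#' `V(IC) = (1/ln 2)^2 (1/a - 1/(a+b) - 1/(a+c) + 1/N)`;
#' `variance = "bate"` instead uses the Bayesian gamma/Dirichlet moment
#' approximation of the classic BCPNN (priors alpha1 = beta1 = 1,
#' alpha = beta = 2, gamma11 = 1), in which case the subtracted term is
#' `E(IC) - 2*sqrt(V(IC))` under those posteriors while the reported `ic`
#' point stays the observed/expected closed form.
#'
#' @inheritParams ror_stat
#' @param variance `"delta"` (default) or `"bate"`.
#' @return data.table with columns `ic`, `ic_minus_2sd`.
#' @export
information_component <- function(a, b, c, d, variance = "delta") {
  variance <- match.arg(variance, base::c("delta", "bate"))
  .recycle_cells(a, b, c, d)
  ok <- .check_cells(a, b, c, d)
  n <- a + b + c + d
  ic <- lo <- rep(NA_real_, length(a))
  ic[ok] <- log2(a[ok] * n[ok] / ((a[ok] + b[ok]) * (a[ok] + c[ok])))
  if (variance == "delta") {
    v <- (1 / log(2))^2 *
      (1 / a - 1 / (a + b) - 1 / (a + c) + 1 / n)
    v <- pmax(v, 0)
    lo[ok] <- ic[ok] - 2 * sqrt(v[ok])
  } else {
    a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
    g <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
    e_ic <- log2((a + g11) * (n + al) * (n + be) /
                   ((n + g) * (a + b + a1) * (a + c + b1)))
    v <- (1 / log(2))^2 * (
      (n - a + g - g11) / ((a + g11) * (1 + n + g)) +
        (n - (a + b) + al - a1) / ((a + b + a1) * (1 + n + al)) +
        (n - (a + c) + be - b1) / ((a + c + b1) * (1 + n + be)))
    lo[ok] <- e_ic[ok] - 2 * sqrt(v[ok])
  }
  data.table(ic = ic, ic_minus_2sd = lo)
}

#' Observed/expected reporting ratio (EBGM-style) with 95% interval
#'
#' `EBGM = aN / ((a+c)(a+b))` with interval
#' `exp(ln EBGM +- 1.96*sqrt(1/a+1/b+1/c+1/d))`; `ebgm05` is the lower
#' bound, the usual signal threshold being `ebgm05 > 2`. This is the
#' unshrunk observed/expected ratio with a Wald-style interval (it obeys
#' `IC = log2(EBGM)` exactly); the two-gamma MGPS posterior mean is out of
#' scope.
#'
#' @inheritParams ror_stat
#' @return data.table with columns `ebgm`, `ebgm05`, `ebgm95`.
#' @export
ebgm_stat <- function(a, b, c, d) {
  .recycle_cells(a, b, c, d)
  ok <- .check_cells(a, b, c, d)
  n <- a + b + c + d
  est <- se <- rep(NA_real_, length(a))
  est[ok] <- a[ok] * n[ok] / ((a[ok] + c[ok]) * (a[ok] + b[ok]))
  se[ok] <- sqrt(1 / a[ok] + 1 / b[ok] + 1 / c[ok] + 1 / d[ok])
  data.table(ebgm = est, ebgm05 = exp(log(est) - .z95 * se),
             ebgm95 = exp(log(est) + .z95 * se))
}

#' All four disproportionality statistics for one or more 2x2 tables
#'
#' Applies the zero-cell policy, then computes ROR, PRR, chi-square, IC and
#' EBGM with their interval bounds. Under the default policy
#' (`zero_policy = "correct"`) a table containing a zero cell has 0.5 added
#' to every cell before the statistics are computed and is flagged
#' `continuity_corrected`; under `"strict"` its statistics are `NA`. The
#' reported cells `a`, `b`, `c`, `d` are always the original counts.
#'
#' @inheritParams ror_stat
#' @param term optional term labels carried through to the output.
#' @param yates continuity-correct the chi-square (default `TRUE`).
#' @param ic_variance variance variant for [information_component()].
#' @param zero_policy `"correct"` (default) or `"strict"`.
#' @return data.table with one row per table: `term` (if given), `a`, `b`,
#'   `c`, `d`, `ror`, `ror_lo`, `ror_hi`, `prr`, `prr_lo`, `prr_hi`,
#'   `chi2`, `ic`, `ic_minus_2sd`, `ebgm`, `ebgm05`,
#'   `continuity_corrected`.
#' @examples
#' signal_stats(3, 7, 97, 9893)
#' @export
signal_stats <- function(a, b, c, d, term = NULL, yates = TRUE,
                         ic_variance = "delta",
                         zero_policy = "correct") {
  zero_policy <- match.arg(zero_policy, base::c("correct", "strict"))
  ic_variance <- match.arg(ic_variance, base::c("delta", "bate"))
  if (inherits(a, "contingency_2x2")) {
    t <- a
    a <- t$a; b <- t$b; c <- t$c; d <- t$d
    if (is.null(term)) term <- t$term
  }
  .recycle_cells(a, b, c, d)
  zero <- !is.na(a) & !is.na(b) & !is.na(c) & !is.na(d) &
    (a == 0 | b == 0 | c == 0 | d == 0)
  aa <- a; bb <- b; cc <- c; dd <- d
  corrected <- rep(FALSE, length(a))
  if (zero_policy == "correct" && any(zero)) {
    aa[zero] <- a[zero] + 0.5
    bb[zero] <- b[zero] + 0.5
    cc[zero] <- c[zero] + 0.5
    dd[zero] <- d[zero] + 0.5
    corrected[zero] <- TRUE
  }
  out <- data.table(a = a, b = b, c = c, d = d)
  if (!is.null(term)) out <- cbind(data.table(term = term), out)
  out <- cbind(out,
               ror_stat(aa, bb, cc, dd),
               prr_stat(aa, bb, cc, dd),
               data.table(chi2 = chi_square(aa, bb, cc, dd, yates = yates)),
               information_component(aa, bb, cc, dd, variance = ic_variance),
               ebgm_stat(aa, bb, cc, dd)[, .(ebgm, ebgm05)],
               data.table(continuity_corrected = corrected))
  out[]
}

#' Apply the four threshold rules to signal statistics
#'
#' Adds the per-algorithm signal flags and the BCPNN strength band:
#' * `ror_signal`: `a >= min_a` and ROR 95% lower bound > 1;
#' * `prr_signal`: `a >= min_a` and PRR 95% lower bound > 1;
#' * `bcpnn_signal`: `IC-2SD > 0`;
#' * `ebgm_signal`: `EBGM05 > ebgm05_cutoff`;
#' * `consensus`: all four simultaneously (the "ADR" rule);
#' * `band`: `-` if `IC-2SD <= 0`, `+` in (0, 1.5], `++` in (1.5, 3],
#'   `+++` above 3.
#' Undefined statistics (`NA`) yield `FALSE` flags and band `-`.
#'
#' @param stats a data.table from [signal_stats()].
#' @param min_a minimum case count gate for ROR/PRR (default 3).
#' @param ebgm05_cutoff threshold on EBGM05 (default 2).
#' @param band_edges upper edges of the `+` and `++` bands
#'   (default `c(1.5, 3)`).
#' @return `stats` with columns `ror_signal`, `prr_signal`,
#'   `bcpnn_signal`, `ebgm_signal`, `consensus`, `band` appended.
#' @export
classify_signal <- function(stats, min_a = 3, ebgm05_cutoff = 2,
                            band_edges = c(1.5, 3)) {
  s <- copy(as.data.table(stats))
  flag <- function(x) !is.na(x) & x
  s[, ror_signal := flag(a >= min_a & ror_lo > 1)]
  s[, prr_signal := flag(a >= min_a & prr_lo > 1)]
  s[, bcpnn_signal := flag(ic_minus_2sd > 0)]
  s[, ebgm_signal := flag(ebgm05 > ebgm05_cutoff)]
  s[, consensus := ror_signal & prr_signal & bcpnn_signal & ebgm_signal]
  s[, band := fcase(
    is.na(ic_minus_2sd) | ic_minus_2sd <= 0, "-",
    ic_minus_2sd <= band_edges[1], "+",
    ic_minus_2sd <= band_edges[2], "++",
    default = "+++")]
  s[]
}

#' Point estimate implied by a log-symmetric confidence interval
#'
#' Any interval of the form `exp(ln(theta) +- z*s)` has its point estimate
#' at the geometric mean of its bounds; this helper recovers it, which is
#' useful for checking published tables that print point and interval.
#'
#' @param lo,hi interval bounds, `0 < lo <= hi`. Vectorized.
#' @return numeric vector `sqrt(lo * hi)`.
#' @examples
#' implied_point_from_ci(6.56, 7.47)
#' @export
implied_point_from_ci <- function(lo, hi) {
  if (any(is.na(lo) | is.na(hi)) || any(lo <= 0) || any(hi <= 0)) {
    stop("interval bounds must be positive", call. = FALSE)
  }
  if (any(lo > hi)) stop("lower bound exceeds upper bound", call. = FALSE)
  sqrt(lo * hi)
}
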