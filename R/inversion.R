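#' Recover the latent cells of a published 2x2 table
#'
#' Published disproportionality tables print, per drug, the co-report count
#' `a` and the derived ROR and PRR, but not the remaining cells `b`, `c`,
#' `d`. Given the database size `N`, those cells are identified by the two
#' rational equations `ROR = ad/(bc)` and `PRR = a(c+d)/(c(a+b))` with
#' `d = N - a - b - c`. Eliminating `c` via the PRR equation reduces the
#' system to one equation in `b`, solved by safeguarded bracketed
#' root-finding. Cells are solved as positive reals: printed statistics are
#' rounded, so exact integer recovery is ill-posed; nearest-integer cells are
#' reported alongside.
#'
#' @param a Published co-report count (>= 1).
#' @param ror,prr Published point estimates (> 0).
#' @param N Total reports in the database.
#' @return An `inversion_result` list: `a`, `b`, `c`, `d` (positive reals),
#'   `b_int`, `c_int`, `d_int` (nearest integers), `residual_ror`,
#'   `residual_prr` (relative plug-back errors against the inputs),
#'   `converged`, and `message` when not converged.
#' @export
solve_latent_cells <- function(a, ror, prr, N = 20754281) {
  a <- unname(as.numeric(a)); ror <- unname(as.numeric(ror))
  prr <- unname(as.numeric(prr)); N <- unname(as.numeric(N))
  stopifnot(a >= 1, ror > 0, prr > 0, N > a)
  fail <- function(msg) {
    structure(list(a = a, b = NA_real_, c = NA_real_, d = NA_real_,
                   b_int = NA_real_, c_int = NA_real_, d_int = NA_real_,
                   residual_ror = NA_real_, residual_prr = NA_real_,
                   converged = FALSE, message = msg),
              class = "inversion_result")
  }
  if (ror <= prr) {
    # d(a+b)/(b(c+d)) = ror/prr <= 1 has no solution with all cells positive
    # unless the ratio exceeds 1 (a, b are a minority of the database).
    return(fail("ror <= prr: no positive solution"))
  }
  cfun <- function(b) a * (N - a - b) / (prr * (a + b))
  f <- function(b) {
    # total-count closure: a + b + c(b) + d(b) - N, with d from the ROR/PRR ratio
    a + b + cfun(b) + (ror / prr) * b * (N - a - b) / (a + b) - N
  }
  lo <- max(1e-9, .Machine$double.eps * N)
  hi <- (N - a) * (1 - 1e-9)
  flo <- f(lo)
  fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    return(fail("no sign change: inconsistent inputs"))
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12, maxiter = 200L)
  b <- root$root
  cc <- cfun(b)
  d <- N - a - b - cc
  if (!(b > 0 && cc > 0 && d > 0)) return(fail("no positive solution"))
  res_ror <- abs(a * d / (b * cc) - ror) / ror
  res_prr <- abs(a * (cc + d) / (cc * (a + b)) - prr) / prr
  structure(list(a = a, b = b, c = cc, d = d,
                 b_int = round(b), c_int = round(cc), d_int = round(d),
                 residual_ror = res_ror, residual_prr = res_prr,
                 converged = res_ror < 1e-6 && res_prr < 1e-6,
                 message = NULL),
            class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<inversion> a=%g b=%.2f c=%.2f d=%.1f (residuals %.1e / %.1e)\n",
                x$a, x$b, x$c, x$d, x$residual_ror, x$residual_prr))
  } else {
    cat(sprintf("<inversion> not converged: %s\n", x$message))
  }
  invisible(x)
}

#' Statistics of a (possibly non-integer) 2x2 table
#'
#' Evaluates ROR with its 95% CI, PRR with its 95% CI, and chi-squared on
#' explicit cells, e.g. the real-valued cells recovered by
#' [solve_latent_cells()]. Shares the code path of [ror_stats()],
#' [prr_stats()] and [chi_square()], so on integer tables it agrees with the
#' pipeline exactly.
#'
#' @param a,b,c,d Positive cell values (reals allowed).
#' @return Tibble with `ror`, `ror_ci_low`, `ror_ci_high`, `prr`,
#'   `prr_ci_low`, `prr_ci_high`, `chi2`.
#' @export
predict_stats <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells <= 0)) {
    stop("all four cells must be positive", call. = FALSE)
  }
  rr <- ror_stats(cells)
  pr <- prr_stats(cells)
  tibble(ror = rr$ror, ror_ci_low = rr$ci_low, ror_ci_high = rr$ci_high,
         prr = pr$prr, prr_ci_low = pr$ci_low, prr_ci_high = pr$ci_high,
         chi2 = chi_square(cells))
}

#' Load the bundled published signal rows
#'
#' A transcription of a published top-50 disproportionality table (drug, `a`,
#' ROR with CI, PRR with CI, chi-squared) used by [consistency_report()].
#'
#' @param path Alternative CSV with the same columns, or `NULL` for the
#'   bundled file.
#' @return Tibble `name`, `a`, `ror`, `ror_ci_low`, `ror_ci_high`, `prr`,
#'   `prr_ci_low`, `prr_ci_high`, `chi2`.
#' @export
load_published_rows <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table3_published.csv", package = "pvsignal")
  }
  readr::read_csv(path, col_types = "ciddddddd", progress = FALSE)
}

#' Consistency check of published rows against their own statistics
#'
#' For each published row, recovers the latent cells from `(a, ROR, PRR, N)`
#' with [solve_latent_cells()], then predicts chi-squared and the ROR CI from
#' those cells and compares them with the printed values. Rows whose printed
#' statistics cannot all come from one 2x2 table show large relative errors;
#' rows exceeding `tol` (default 1%, the agreement attainable given
#' two-decimal rounding of the printed inputs) are flagged inconsistent.
#'
#' @param rows Tibble as returned by [load_published_rows()].
#' @param N Database size used for the inversion.
#' @param tol Relative-error threshold for the `consistent` flag.
#' @return Tibble per row: recovered cells, residuals, predicted vs printed
#'   `chi2` and ROR CI bounds with relative errors, `converged`,
#'   `consistent`.
#' @export
consistency_report <- function(rows = load_published_rows(), N = 20754281,
                               tol = 0.01) {
  if (!nrow(rows)) {
    return(tibble(name = character(), a = integer(), converged = logical(),
                  b = double(), c = double(), d = double(),
                  pred_chi2 = double(), chi2_rel_err = double(),
                  pred_ror_ci_low = double(), ror_ci_low_rel_err = double(),
                  pred_ror_ci_high = double(), ror_ci_high_rel_err = double(),
                  consistent = logical()))
  }
  purrr::pmap(rows, function(name, a, ror, ror_ci_low, ror_ci_high,
                             prr, prr_ci_low, prr_ci_high, chi2, ...) {
    inv <- solve_latent_cells(a, ror, prr, N)
    if (!inv$converged) {
      return(tibble(name = name, a = a, converged = FALSE,
                    b = NA_real_, c = NA_real_, d = NA_real_,
                    pred_chi2 = NA_real_, chi2_rel_err = NA_real_,
                    pred_ror_ci_low = NA_real_, ror_ci_low_rel_err = NA_real_,
                    pred_ror_ci_high = NA_real_, ror_ci_high_rel_err = NA_real_,
                    consistent = FALSE))
    }
    pred <- predict_stats(inv$a, inv$b, inv$c, inv$d)
    rel <- function(est, pub) abs(est - pub) / abs(pub)
    errs <- c(rel(pred$chi2, chi2), rel(pred$ror_ci_low, ror_ci_low),
              rel(pred$ror_ci_high, ror_ci_high))
    tibble(name = name, a = a, converged = TRUE,
           b = inv$b, c = inv$c, d = inv$d,
           pred_chi2 = pred$chi2, chi2_rel_err = errs[1],
           pred_ror_ci_low = pred$ror_ci_low, ror_ci_low_rel_err = errs[2],
           pred_ror_ci_high = pred$ror_ci_high, ror_ci_high_rel_err = errs[3],
           consistent = all(errs <= tol))
  }) |> dplyr::bind_rows()
}
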