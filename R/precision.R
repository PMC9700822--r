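# Modified coefficients of variation from posterior quantiles, and
# cell-by-cell precision comparison between the BBS-only and joint models.

#' Modified coefficient of variation (abundance parameters)
#'
#' `(q975 - q025) / |q50|`: the 95% credible-interval width relative to the
#' absolute posterior median. Smaller is more precise. Cells whose median is
#' numerically zero (|q50| < 1e-12) return `Inf` and are flagged by
#' [cv_table()] (the ratio is undefined there).
#'
#' @param q025,q50,q975 Posterior quantiles (vectors).
#' @return Numeric CV values.
#' @examples
#' cv_relative(1, 2, 5)    # 2
#' cv_relative(-3, -1, 1)  # 4
#' @export
cv_relative <- function(q025, q50, q975) {
  if (any(q025 > q50 + 1e-12) || any(q50 > q975 + 1e-12))
    stop("quantiles must be ordered q025 <= q50 <= q975")
  ifelse(abs(q50) < 1e-12, Inf, (q975 - q025) / abs(q50))
}

#' Credible-interval width (trend parameters)
#'
#' Trends are compared by the raw 95% interval width `q975 - q025`, with no
#' median denominator: trends near zero would make a relative CV explode.
#'
#' @param q025,q975 Posterior quantiles (vectors).
#' @return Numeric widths.
#' @export
cv_width <- function(q025, q975) {
  if (any(q025 > q975 + 1e-12)) stop("quantiles must be ordered q025 <= q975")
  q975 - q025
}

#' Per-cell CV table for a fitted model
#'
#' Computes the relative CV of mean relative abundance (`alpha`, on the
#' posterior of `alpha` itself) and of year-specific relative abundance
#' (`gamma`, per cell-year on the natural scale), and the interval width of
#' the trend (`beta`), for every modelled cell.
#'
#' @param fit An `"abund_fit"`.
#' @return Data frame of class `"abund_cv"` with columns `cell_id`, `param`
#'   (`"alpha"`, `"beta"`, or `"gamma"`), `year` (`NA` except for gamma),
#'   `cv`, `flagged` (degenerate median), and attribute `model`.
#' @export
cv_table <- function(fit) {
  stopifnot(inherits(fit, "abund_fit"))
  a <- predict(fit, "alpha")
  b <- predict(fit, "beta")
  g <- predict(fit, "gamma")
  out <- rbind(
    data.frame(cell_id = a$cell_id, param = "alpha", year = NA_integer_,
               cv = cv_relative(a$q025, a$q50, a$q975)),
    data.frame(cell_id = b$cell_id, param = "beta", year = NA_integer_,
               cv = cv_width(b$q025, b$q975)),
    data.frame(cell_id = g$cell_id, param = "gamma", year = g$year,
               cv = cv_relative(g$q025, g$q50, g$q975)))
  out$flagged <- !is.finite(out$cv)
  attr(out, "model") <- fit$model
  class(out) <- c("abund_cv", "data.frame")
  out
}

# mean over years of the per-cell gamma CVs (one number per cell); flagged
# cell-years are excluded, a cell with every year flagged stays flagged.
.gamma_cell_cv <- function(cv) {
  g <- cv[cv$param == "gamma", ]
  sp <- split(g, g$cell_id)
  data.frame(cell_id = as.integer(names(sp)),
             cv = vapply(sp, function(d) {
               ok <- !d$flagged
               if (!any(ok)) Inf else mean(d$cv[ok])
             }, numeric(1)),
             row.names = NULL)
}

#' Compare precision between the BBS-only and joint models
#'
#' Subtracts the joint-model CV from the BBS-only CV for each cell and
#' parameter (positive difference = joint more precise) and reports, per
#' parameter, the proportion of cells where the joint CV is strictly lower.
#' Year-specific abundance is aggregated to one CV per cell as the mean of
#' its per-year CVs before differencing. Cells with a degenerate
#' (zero-median) CV in either model are excluded from the proportions and
#' counted. Optionally stratifies the per-cell differences by quartile of
#' the joint model's `alpha` estimates, by distance to range edge, and by
#' per-cell survey effort.
#'
#' @param cv_bbs,cv_joint CV tables from [cv_table()] for the two models
#'   (same cell set).
#' @param abundance Optional named vector (by cell id) of joint-model
#'   `alpha` posterior medians for quartile stratification.
#' @param dist_edge,n_routes,n_checklists Optional named vectors (by cell
#'   id) carried into the per-cell output.
#' @return A list of class `"abund_cv_comparison"`: `cells` (per-cell table:
#'   `cell_id`, `param`, `cv_bbs`, `cv_joint`, `diff`, plus any strata
#'   columns), `proportion_improved` (named per-parameter),
#'   `n_excluded` (flagged cells per parameter), and `quartile_summary`
#'   (mean difference by abundance quartile) when `abundance` is given.
#' @examples
#' # three cells, CVs 2,3,4 (BBS) vs 1,3.5,2 (joint): 2/3 improved
#' @export
compare_models <- function(cv_bbs, cv_joint, abundance = NULL,
                           dist_edge = NULL, n_routes = NULL,
                           n_checklists = NULL) {
  per_cell <- function(cv) {
    rbind(cv[cv$param %in% c("alpha", "beta"),
             c("cell_id", "param", "cv")],
          cbind(.gamma_cell_cv(cv)[, "cell_id", drop = FALSE],
                param = "gamma", cv = .gamma_cell_cv(cv)$cv))
  }
  a <- per_cell(cv_bbs); b <- per_cell(cv_joint)
  a <- a[order(a$param, a$cell_id), ]; b <- b[order(b$param, b$cell_id), ]
  if (!identical(a$cell_id, b$cell_id) || !identical(a$param, b$param))
    stop("the two CV tables cover different cells or parameters")
  cells <- data.frame(cell_id = a$cell_id, param = a$param,
                      cv_bbs = a$cv, cv_joint = b$cv,
                      diff = a$cv - b$cv, row.names = NULL)
  ok <- is.finite(cells$cv_bbs) & is.finite(cells$cv_joint)
  prop <- tapply(ok & (cells$cv_joint < cells$cv_bbs), cells$param, sum) /
    pmax(tapply(ok, cells$param, sum), 1)
  n_excl <- tapply(!ok, cells$param, sum)
  add_stratum <- function(v, nm) {
    if (!is.null(v)) cells[[nm]] <<- unname(v[as.character(cells$cell_id)])
  }
  quart <- NULL
  if (!is.null(abundance)) {
    qb <- stats::quantile(abundance, c(0.25, 0.5, 0.75))
    qa <- stats::setNames(1L + findInterval(abundance, qb), names(abundance))
    cells$abundance_quartile <- unname(qa[as.character(cells$cell_id)])
    quart <- aggregate(diff ~ param + abundance_quartile,
                       data = cells[ok, ], FUN = mean)
  }
  add_stratum(dist_edge, "dist_edge_km")
  add_stratum(n_routes, "n_routes")
  add_stratum(n_checklists, "n_checklists")
  structure(list(cells = cells,
                 proportion_improved = c(prop),
                 n_excluded = c(n_excl),
                 quartile_summary = quart),
            class = "abund_cv_comparison")
}

#' @export
print.abund_cv_comparison <- function(x, ...) {
  cat("Precision comparison (CV[BBS-only] - CV[joint]; positive = joint",
      "more precise)\n")
  cat("Proportion of cells improved by the joint model:\n")
  print(round(x$proportion_improved, 3))
  if (any(x$n_excluded > 0)) {
    cat("Cells excluded (degenerate median):\n")
    print(x$n_excluded)
  }
  invisible(x)
}
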