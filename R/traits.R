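#' Canonical trait subscale names
#' @return Character vector of the eight subscale names.
#' @export
trait_names <- function() ppi_subscale_stats()$trait

#' Optimal-scaling transform (z-scores times 10)
#'
#' Numeric-level optimal scaling used before variable selection: each column
#' is centered, divided by its SD, and multiplied by 10. With every variable
#' at numeric level the full alternating-least-squares quantification reduces
#' to exactly this standardization, so this transform is the whole machinery.
#' The default SD denominator is the population (n) convention; Pearson
#' correlations downstream are invariant to the choice.
#'
#' @param table A data.frame (numeric columns are scaled; any `subject`
#'   column is passed through) or numeric matrix/vector.
#' @param sd_denom `"population"` (n, default) or `"sample"` (n - 1).
#' @return The same structure with scaled numeric columns (mean 0,
#'   population/sample SD 10).
#' @export
optimal_scale <- function(table, sd_denom = c("population", "sample")) {
  sd_denom <- match.arg(sd_denom)
  scale_col <- function(x, name) {
    m <- mean(x)
    s <- if (sd_denom == "population") {
      sqrt(mean((x - m)^2))
    } else {
      stats::sd(x)
    }
    if (!is.finite(s) || s == 0) {
      stop("column '", name, "' is constant; cannot optimal-scale",
           call. = FALSE)
    }
    (x - m) / s * 10
  }
  if (is.numeric(table) && is.null(dim(table))) {
    return(scale_col(table, "x"))
  }
  table <- as.data.frame(table)
  for (nm in names(table)) {
    if (nm == "subject") next
    if (is.numeric(table[[nm]])) table[[nm]] <- scale_col(table[[nm]], nm)
  }
  table
}

# ---- lasso homotopy ---------------------------------------------------------
# Exact piecewise-linear solution path of
#   min_b 1/2 ||y - X b||^2 + lambda ||b||_1   (no intercept; caller centers)
# by decreasing lambda from lambda_max to 0, tracking active-set additions
# and sign-change drops. With 8 predictors the path has a handful of knots;
# coefficients between knots are linear in lambda, so the solution at any L1
# budget is recovered exactly by interpolation. The standardized sum of
# coefficients (SSC) axis used downstream is the L1 norm as a fraction of the
# unconstrained least-squares norm.
lasso_homotopy <- function(X, y, tol = 1e-12) {
  X <- as.matrix(X)
  p <- ncol(X)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  qx <- qr(X)
  if (qx$rank < p) {
    stop("predictors are rank-deficient; the unconstrained solution is not ",
         "unique", call. = FALSE)
  }

  lambda <- max(abs(Xty))
  knots_lambda <- lambda
  knots_beta <- matrix(0, 1, p)
  active <- which.max(abs(Xty))
  sgn <- sign(Xty[active])

  repeat {
    A <- active
    GA <- XtX[A, A, drop = FALSE]
    u <- solve(GA, Xty[A])
    d <- solve(GA, sgn)
    # b_A(lam) = u - lam * d; correlations of inactive j:
    # c_j(lam) = (Xty[j] - XtX[j,A] u) + lam * XtX[j,A] d = a_j + lam * g_j
    events_lam <- numeric(0)
    events_what <- list()
    for (idx in seq_along(A)) {
      if (abs(d[idx]) > tol) {
        lam0 <- u[idx] / d[idx]
        if (lam0 > tol && lam0 < lambda - tol) {
          events_lam <- c(events_lam, lam0)
          events_what <- c(events_what, list(list(type = "drop", j = A[idx])))
        }
      }
    }
    inactive <- setdiff(seq_len(p), A)
    if (length(inactive)) {
      a_j <- Xty[inactive] - drop(XtX[inactive, A, drop = FALSE] %*% u)
      g_j <- drop(XtX[inactive, A, drop = FALSE] %*% d)
      for (idx in seq_along(inactive)) {
        for (cand in c(a_j[idx] / (1 - g_j[idx]),
                       -a_j[idx] / (1 + g_j[idx]))) {
          if (is.finite(cand) && cand > tol && cand < lambda - tol) {
            events_lam <- c(events_lam, cand)
            events_what <- c(events_what,
                             list(list(type = "add", j = inactive[idx])))
          }
        }
      }
    }
    lam_next <- if (length(events_lam)) max(events_lam) else 0
    pick <- if (length(events_lam)) which.max(events_lam) else 0L

    b <- numeric(p)
    b[A] <- u - lam_next * d
    knots_lambda <- c(knots_lambda, lam_next)
    knots_beta <- rbind(knots_beta, b)
    if (lam_next <= tol) break
    ev <- events_what[[pick]]
    if (ev$type == "drop") {
      keep <- active != ev$j
      active <- active[keep]
      sgn <- sgn[keep]
      if (length(active) == 0) {
        # restart from the largest remaining correlation
        cvec <- Xty - drop(XtX %*% b)
        active <- which.max(abs(cvec))
        sgn <- sign(cvec[active])
      }
    } else {
      cvec_j <- Xty[ev$j] - drop(XtX[ev$j, A, drop = FALSE] %*%
                                   (u - lam_next * d))
      active <- c(active, ev$j)
      sgn <- c(sgn, sign(cvec_j))
    }
    lambda <- lam_next
  }
  rownames(knots_beta) <- NULL
  list(lambda = knots_lambda, beta = knots_beta,
       beta_ols = knots_beta[nrow(knots_beta), ])
}

# Coefficients at an L1 budget equal to `fraction` of the unconstrained
# solution's L1 norm, by exact interpolation between homotopy knots.
homotopy_coef_at_fraction <- function(hom, fraction) {
  l1 <- rowSums(abs(hom$beta))
  target <- fraction * l1[length(l1)]
  if (fraction >= 1) return(hom$beta[nrow(hom$beta), ])
  if (target <= 0) return(numeric(ncol(hom$beta)))
  k <- max(which(l1 <= target + 1e-12))
  if (k == length(l1)) return(hom$beta[k, ])
  span <- l1[k + 1] - l1[k]
  t <- if (span <= 0) 0 else (target - l1[k]) / span
  (1 - t) * hom$beta[k, ] + t * hom$beta[k + 1, ]
}

#' Lasso path over the standardized-sum-of-coefficients grid
#'
#' Solves, for each shrinkage fraction f on the 0.0-1.0 grid in steps of
#' 0.02 (51 levels), the least-squares problem subject to an L1 bound equal
#' to f times the unconstrained solution's L1 norm. The path is computed
#' exactly by homotopy, so each constrained solution is exact up to floating
#' point (well inside 1e-8).
#'
#' @param X Predictor matrix (columns already optimal-scaled; no intercept).
#' @param y Response vector (optimal-scaled).
#' @param fractions Shrinkage fractions (default `seq(0, 1, by = 0.02)`).
#' @return An object of class `lasso_path`: `fractions`, `coefficients`
#'   (length(fractions) x p matrix), `beta_ols`, `homotopy`.
#' @export
lasso_path <- function(X, y, fractions = seq(0, 1, by = 0.02)) {
  X <- as.matrix(X)
  if (stats::var(y) == 0) stop("response has zero variance", call. = FALSE)
  if (any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  hom <- lasso_homotopy(X, y)
  co <- t(vapply(fractions, function(f) homotopy_coef_at_fraction(hom, f),
                 numeric(ncol(X))))
  colnames(co) <- colnames(X)
  structure(list(fractions = fractions, coefficients = co,
                 beta_ols = hom$beta_ols, homotopy = hom),
            class = "lasso_path")
}

#' Select the optimal shrinkage level by .632 bootstrap
#'
#' For each shrinkage fraction, estimates expected squared prediction error
#' as `0.368 * apparent + 0.632 * out-of-bag`, where the apparent error is
#' the training MSE of the constrained fit on the full data and the
#' out-of-bag term averages, over `B` bootstrap samples, the MSE of the fit
#' refit on each bootstrap sample (centered within the sample, its own L1
#' reference norm) evaluated on that sample's out-of-bag subjects. Bootstrap
#' samples whose out-of-bag set is empty are redrawn (and counted). The
#' selected level is the error minimizer; ties break toward the smaller
#' (more parsimonious) level. Deterministic given `seed`.
#'
#' @param X,y Optimal-scaled predictors and response.
#' @param fractions Shrinkage grid (default 51 levels, step 0.02).
#' @param B Bootstrap samples (default 100).
#' @param seed Integer seed.
#' @return A list of class `lasso_selection`: `fraction` (selected level),
#'   `coefficients` (full-data fit at that level), `predictors` (names with
#'   nonzero coefficients), `errors` (data.frame fraction/apparent/oob/
#'   err632), `se_oob`, `n_redrawn`, `path`.
#' @export
select_optimal <- function(X, y, fractions = seq(0, 1, by = 0.02), B = 100,
                           seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  path <- lasso_path(X, y, fractions)
  nf <- length(fractions)
  pred_full <- X %*% t(path$coefficients)          # n x nf
  apparent <- colMeans((y - pred_full)^2)

  oob_err <- matrix(NA_real_, B, nf)
  n_redrawn <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      # draw until the sample has out-of-bag subjects and a full-rank design
      repeat {
        if (n_redrawn > 1000L * B) {
          stop("bootstrap resampling failed repeatedly (n too small ",
               "relative to the predictor count?)", call. = FALSE)
        }
        idx <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), unique(idx))
        if (length(oob) == 0) {
          n_redrawn <- n_redrawn + 1L
          next
        }
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        xbar <- colMeans(Xb)
        ybar <- mean(yb)
        hom_b <- tryCatch(lasso_homotopy(sweep(Xb, 2, xbar), yb - ybar),
                          error = function(e) NULL)
        if (!is.null(hom_b)) break
        n_redrawn <- n_redrawn + 1L
      }
      cb <- t(vapply(fractions,
                     function(f) homotopy_coef_at_fraction(hom_b, f),
                     numeric(ncol(X))))
      Xo <- sweep(X[oob, , drop = FALSE], 2, xbar)
      pred <- Xo %*% t(cb) + ybar                  # |oob| x nf
      oob_err[b, ] <- colMeans((y[oob] - pred)^2)
    }
  })
  oob_mean <- colMeans(oob_err)
  err632 <- 0.368 * apparent + 0.632 * oob_mean
  best <- which.min(err632)                        # first minimum = smallest f
  coefs <- path$coefficients[best, ]
  structure(list(fraction = fractions[best],
                 coefficients = coefs,
                 predictors = names(coefs)[abs(coefs) > 1e-8],
                 errors = data.frame(fraction = fractions,
                                     apparent = apparent,
                                     oob = oob_mean,
                                     err632 = err632),
                 se_oob = apply(oob_err, 2, stats::sd) / sqrt(B),
                 n_redrawn = n_redrawn,
                 path = path),
            class = "lasso_selection")
}

#' Pearson correlation with percentile bootstrap confidence interval
#'
#' Pearson r on the original data plus a nonparametric percentile CI
#' (2.5/97.5) over `B` paired resamples; a correlation is flagged
#' significant iff the CI excludes 0 (both bounds on the same side).
#' Degenerate resamples (zero variance in either variable) are redrawn and
#' counted.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @param B Bootstrap samples (default 10000).
#' @param seed Integer seed.
#' @return A list of class `bootstrap_corr`: `r`, `ci` (lower, upper),
#'   `significant`, `B`, `n_redrawn`.
#' @export
bootstrap_corr <- function(x, y, B = 10000, seed = 1L) {
  n <- length(x)
  if (length(y) != n || n < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  r <- stats::cor(x, y)
  rs <- withr::with_seed(seed, {
    out <- numeric(B)
    filled <- 0L
    redrawn <- 0L
    while (filled < B) {
      m <- min(B - filled, 2000L)
      idx <- matrix(sample.int(n, n * m, replace = TRUE), n, m)
      xm <- matrix(x[idx], n, m)
      ym <- matrix(y[idx], n, m)
      xc <- sweep(xm, 2, colMeans(xm))
      yc <- sweep(ym, 2, colMeans(ym))
      sx <- sqrt(colSums(xc^2))
      sy <- sqrt(colSums(yc^2))
      ok <- sx > 0 & sy > 0
      redrawn <- redrawn + sum(!ok)
      vals <- (colSums(xc * yc) / (sx * sy))[ok]
      take <- seq_len(min(length(vals), B - filled))
      out[filled + take] <- vals[take]
      filled <- filled + length(take)
    }
    attr(out, "redrawn") <- redrawn
    out
  })
  ci <- unname(stats::quantile(rs, c(0.025, 0.975)))
  structure(list(r = r, ci = ci,
                 significant = ci[1] > 0 || ci[2] < 0,
                 B = B, n_redrawn = attr(rs, "redrawn")),
            class = "bootstrap_corr")
}

#' Normality check of a score distribution
#'
#' One-sample Kolmogorov-Smirnov-type test against a normal with mean and SD
#' estimated from the sample. Because the reference parameters are
#' estimated, the default p-value uses the Lilliefors correction (via
#' \pkg{nortest}), which is calibrated in exactly this situation; the
#' uncorrected asymptotic KS p (conservative here) is available as
#' `method = "asymptotic"`.
#'
#' @param x Numeric vector, n >= 5, non-constant.
#' @param method `"lilliefors"` (default) or `"asymptotic"`.
#' @return A list with `statistic` (the KS distance, in [0, 1]), `p`, and
#'   `method`.
#' @export
ks_normality <- function(x, method = c("lilliefors", "asymptotic")) {
  method <- match.arg(method)
  if (length(x) < 5) stop("need n >= 5", call. = FALSE)
  if (stats::sd(x) == 0) stop("input is constant", call. = FALSE)
  if (method == "lilliefors") {
    ht <- nortest::lillie.test(x)
  } else {
    ht <- suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  }
  list(statistic = unname(ht$statistic), p = unname(ht$p.value),
       method = method)
}

#' Trait-association stage for one model parameter
#'
#' Runs the full association procedure that links trait scores to a fitted
#' model parameter: optimal scaling (z x 10) of traits and parameter, lasso
#' variable selection over the 51-level shrinkage grid with .632-bootstrap
#' model choice, then for each selected trait a Pearson correlation with a
#' percentile bootstrap CI, plus normality checks of all eight trait score
#' distributions and of the parameter.
#'
#' @param traits data.frame with the eight trait columns (a `subject` column
#'   is ignored).
#' @param param_values Numeric vector of per-subject parameter values
#'   (same order as `traits` rows).
#' @param target Label for the parameter (`"gamma_social"` or
#'   `"gamma_reward"`).
#' @param B_select Bootstrap samples for the .632 selection (default 100).
#' @param B_corr Bootstrap samples for correlation CIs (default 10000).
#' @param seed Integer seed.
#' @return An object of class `association_result`: `target`, `selection`
#'   (the `lasso_selection`), `correlations` (data.frame trait/r/ci_lower/
#'   ci_upper/significant), `normality` (data.frame variable/statistic/p).
#' @export
associate_traits <- function(traits, param_values,
                             target = c("gamma_social", "gamma_reward"),
                             B_select = 100, B_corr = 10000, seed = 1L) {
  target <- match.arg(target)
  tcols <- intersect(trait_names(), names(traits))
  if (length(tcols) < 2) {
    stop("traits table must contain the named subscale columns", call. = FALSE)
  }
  if (anyNA(traits[tcols]) || anyNA(param_values)) {
    stop("traits and parameter values must be complete", call. = FALSE)
  }
  if (nrow(traits) != length(param_values)) {
    stop("traits rows and param_values length differ", call. = FALSE)
  }
  X <- as.matrix(optimal_scale(traits[tcols]))
  yv <- optimal_scale(param_values)
  sel <- select_optimal(X, yv, B = B_select, seed = derive_seed(seed, 1L))

  cors <- lapply(seq_along(sel$predictors), function(i) {
    nm <- sel$predictors[i]
    bc <- bootstrap_corr(traits[[nm]], param_values, B = B_corr,
                         seed = derive_seed(seed, 100L + i))
    data.frame(trait = nm, r = bc$r, ci_lower = bc$ci[1],
               ci_upper = bc$ci[2], significant = bc$significant,
               stringsAsFactors = FALSE)
  })
  cors <- if (length(cors)) do.call(rbind, cors) else
    data.frame(trait = character(0), r = numeric(0), ci_lower = numeric(0),
               ci_upper = numeric(0), significant = logical(0))

  norm_vars <- c(tcols, target)
  norm_vals <- c(lapply(tcols, function(nm) traits[[nm]]),
                 list(param_values))
  normality <- do.call(rbind, lapply(seq_along(norm_vars), function(i) {
    ks <- ks_normality(norm_vals[[i]])
    data.frame(variable = norm_vars[i], statistic = ks$statistic, p = ks$p,
               stringsAsFactors = FALSE)
  }))

  structure(list(target = target, selection = sel, correlations = cors,
                 normality = normality),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("Association result for", x$target, "\n")
  cat("optimal shrinkage fraction:", x$selection$fraction, "\n")
  if (length(x$selection$predictors) == 0) {
    cat("no traits selected\n")
  } else {
    cat("selected traits:", paste(x$selection$predictors, collapse = ", "),
        "\n")
    print(x$correlations, row.names = FALSE)
  }
  invisible(x)
}
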