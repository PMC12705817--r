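# Random-intercept linear mixed model, fit by profiled REML.
#
# The pipeline fits the same tiny model class (one grouping factor, a handful
# of fixed effects) hundreds of times per network and thousands of times in
# the permutation null, so the fitter works on per-subject sufficient
# statistics and profiles the REML criterion down to a 1-D optimization over
# the variance ratio theta = sigma_u^2 / sigma_e^2.
#
# For subject j with n_j observations, V_j = sigma_e^2 (I + theta J) and
# V_j^{-1} = (1/sigma_e^2) (I - c_j J), c_j = theta / (1 + theta n_j). All
# GLS quantities reduce to per-subject crossproducts, and sigma_e^2 is
# profiled out analytically; the remaining criterion
#   (n - p) log r(theta) + sum_j log(1 + theta n_j) + log det M(theta)
# is minimized over log(theta).

fit_lmm_ranint <- function(y, X, subject) {
  stopifnot(length(y) == nrow(X), length(subject) == length(y))
  keep <- stats::complete.cases(y, X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; subject <- subject[keep]
  subj <- factor(subject)
  n <- length(y); p <- ncol(X); S <- nlevels(subj)
  if (n <= p) stop("too few observations for ", p, " fixed effects")
  # sufficient statistics
  A <- crossprod(X)              # p x p
  b <- crossprod(X, y)           # p x 1
  qyy <- sum(y * y)
  Sx <- rowsum(X, subj)          # S x p  (per-subject column sums)
  ty <- rowsum(y, subj)[, 1L]    # per-subject y sums
  nj <- tabulate(subj)

  quantities <- function(theta) {
    cj <- theta / (1 + theta * nj)
    M <- A - crossprod(Sx * sqrt(cj))
    v <- b - crossprod(Sx, cj * ty)
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    beta <- backsolve(R, forwardsolve(t(R), v))
    r <- qyy - sum(cj * ty^2) - sum(v * beta)
    list(M = M, R = R, beta = drop(beta), r = max(r, 1e-300),
         logdetM = 2 * sum(log(diag(R))), cj = cj)
  }
  crit <- function(ltheta) {
    th <- exp(ltheta)
    qq <- quantities(th)
    if (is.null(qq)) return(1e300)
    (n - p) * log(qq$r) + sum(log1p(th * nj)) + qq$logdetM
  }
  crit0 <- {
    qq <- quantities(0)
    if (is.null(qq)) stop("singular fixed-effect design (constant predictor?)")
    (n - p) * log(qq$r) + qq$logdetM
  }
  opt <- stats::optimize(crit, interval = c(-12, 12), tol = 1e-7)
  if (opt$objective < crit0 - 1e-10) {
    theta <- exp(opt$minimum)
    singular <- FALSE
  } else {
    theta <- 0
    singular <- TRUE   # zero intercept variance: the fit degenerates to OLS
  }
  qq <- quantities(theta)
  sigma2 <- qq$r / (n - p)
  Minv <- chol2inv(qq$R)
  se <- sqrt(sigma2 * diag(Minv))
  tval <- qq$beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  list(beta = qq$beta, se = se, t = tval, p = pval,
       theta = theta, sigma2_e = sigma2, sigma2_u = theta * sigma2,
       singular = singular, n_obs = n, n_subjects = S, df = n - p)
}

#' Estimate a cross-sectional network edge by mixed-effects regression
#'
#' Fits a random-intercept model `y_ij = b0 + b1 x_ij + u_j + e_ij` by
#' restricted maximum likelihood, where `u_j` is a per-subject intercept
#' absorbing between-subject differences in item intensity. The fixed slope
#' `b1` is the edge weight; its Wald p-value (t reference with residual
#' degrees of freedom) feeds the false-discovery-rate pruning.
#'
#' When the intercept variance is estimated at zero the fit coincides with
#' ordinary least squares and is flagged `singular`.
#'
#' @param y,x Numeric observation vectors (paired; `NA`s dropped pairwise).
#' @param subject_ids Grouping vector, same length as `y`.
#' @param scale Z-score `x` and `y` over the pooled observations before
#'   fitting (default TRUE), making slopes comparable across item pairs.
#'   Use `scale = FALSE` to estimate the slope on the original scale, e.g.
#'   when comparing against a known generative coefficient.
#' @param moderator Optional per-observation subject-level score; when given,
#'   the model `y = b0 + b1 x + b2 s + b3 (x s) + u_j + e` is fitted and the
#'   interaction coefficient `b3` is the reported effect.
#' @return An object of class `edge_estimate`: a list with `beta0`, `beta1`,
#'   (`beta2`, `beta3` for moderated fits), `estimate` (the reported
#'   coefficient), `se`, `p`, `singular`, `n_obs`, `n_subjects`.
#' @export
#' @examples
#' set.seed(1)
#' subj <- rep(1:10, each = 8)
#' x <- rnorm(80)
#' y <- 0.5 * x + rnorm(10)[subj] + rnorm(80, sd = 0.5)
#' fit_edge(y, x, subj, scale = FALSE)$beta1
fit_edge <- function(y, x, subject_ids, scale = TRUE, moderator = NULL) {
  keep <- !is.na(y) & !is.na(x)
  if (!is.null(moderator)) keep <- keep & !is.na(moderator)
  y <- y[keep]; x <- x[keep]; subject_ids <- subject_ids[keep]
  if (!is.null(moderator)) moderator <- moderator[keep]
  if (length(y) < 4L) stop("too few paired observations")
  if (stats::sd(x) == 0) stop("predictor is constant")
  tab <- table(subject_ids)
  if (sum(tab >= 2L) < 1L) stop("no subject with >= 2 paired observations")
  if (scale) {
    x <- as.numeric(base::scale(x))
    y <- as.numeric(base::scale(y))
  }
  if (is.null(moderator)) {
    X <- cbind(`(Intercept)` = 1, x = x)
    fit <- fit_lmm_ranint(y, X, subject_ids)
    out <- list(beta0 = fit$beta[1L], beta1 = fit$beta[2L],
                estimate = fit$beta[2L], se = fit$se[2L], p = fit$p[2L],
                lagged = FALSE, moderated = FALSE)
  } else {
    s <- moderator
    subj_score <- tapply(s, subject_ids, function(v) v[1L])
    if (any(abs(tapply(s, subject_ids, stats::sd, na.rm = TRUE)) > 1e-10,
            na.rm = TRUE)) {
      stop("moderator must be constant within subject")
    }
    if (stats::sd(subj_score) == 0) stop("moderator is constant across subjects")
    # z-score at the subject level (one value per subject), then expand
    zs <- as.numeric(base::scale(as.numeric(subj_score)))
    names(zs) <- names(subj_score)
    s <- zs[as.character(subject_ids)]
    X <- cbind(`(Intercept)` = 1, x = x, s = s, `x:s` = x * s)
    fit <- fit_lmm_ranint(y, X, subject_ids)
    out <- list(beta0 = fit$beta[1L], beta1 = fit$beta[2L],
                beta2 = fit$beta[3L], beta3 = fit$beta[4L],
                estimate = fit$beta[4L], se = fit$se[4L], p = fit$p[4L],
                lagged = FALSE, moderated = TRUE)
  }
  out <- c(out, list(singular = fit$singular, theta = fit$theta,
                     sigma2_e = fit$sigma2_e, sigma2_u = fit$sigma2_u,
                     n_obs = fit$n_obs, n_subjects = fit$n_subjects))
  class(out) <- "edge_estimate"
  out
}

#' Estimate a moderated network edge
#'
#' Convenience wrapper around [fit_edge()] adding a subject-level score `s`
#' (z-scored across subjects) and its interaction with the predictor; the
#' reported coefficient is the interaction `b3`, quantifying how the
#' within-subject coupling between `x` and `y` changes with `s`.
#'
#' @inheritParams fit_edge
#' @param s Per-subject score: either one value per observation (constant
#'   within subject) or a named vector indexed by subject id.
#' @return An `edge_estimate` with `beta3` as the reported `estimate`.
#' @export
fit_moderated_edge <- function(y, x, subject_ids, s, scale = TRUE) {
  if (!is.null(names(s)) && length(s) != length(y)) {
    s <- unname(s[as.character(subject_ids)])
    if (anyNA(s)) stop("score missing for some subject(s)")
  }
  fit_edge(y, x, subject_ids, scale = scale, moderator = s)
}

#' @export
print.edge_estimate <- function(x, ...) {
  kind <- if (isTRUE(x$moderated)) "moderated (b3)" else "slope (b1)"
  cat(sprintf("<edge_estimate> %s = %.4f (se %.4f, p %.3g), n = %d obs / %d subjects%s\n",
              kind, x$estimate, x$se, x$p, x$n_obs, x$n_subjects,
              if (isTRUE(x$singular)) " [singular: OLS]" else ""))
  invisible(x)
}
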