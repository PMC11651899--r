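#' Priors for the dyadic multi-membership model
#'
#' Weakly-informative defaults interpreting "default, uninformative" priors:
#' Normal(0, sd_beta^2) on the intercept and coefficients, half-Student-t(3,
#' 0, 2.5) on both the residual scale sigma and the member random-effect scale
#' sigma_u. The half-t priors are represented in Huang-Wand auxiliary form, so
#' all full conditionals stay in closed form.
#'
#' @param sd_beta Prior standard deviation of intercept and coefficients.
#' @param scale_sigma,scale_sigma_u Scale of the half-t(3) priors on sigma and
#'   sigma_u.
#' @param nu Degrees of freedom of the half-t priors.
#' @return List of prior settings.
#' @export
dyad_mm_prior <- function(sd_beta = 5, scale_sigma = 2.5, scale_sigma_u = 2.5,
                          nu = 3) {
  stopifnot(sd_beta > 0, scale_sigma > 0, scale_sigma_u > 0, nu > 0)
  list(sd_beta = sd_beta, scale_sigma = scale_sigma,
       scale_sigma_u = scale_sigma_u, nu = nu)
}

.rinvgamma1 <- function(shape, rate) 1 / stats::rgamma(1L, shape = shape, rate = rate)

## One Gibbs chain. All conditionals are exact:
##   (beta, u) | s2, s2u  ~ Normal  (single joint block over the full design
##                                   W = [X, Z]; W'W and W'y are constant, so
##                                   each sweep costs one (p+M) Cholesky)
##   s2, s2u              ~ Inv-Gamma via the Huang-Wand half-t auxiliaries
## The joint block removes the intercept <-> mean(u) random-walk coupling
## that makes separately-blocked samplers mix slowly.
.gibbs_chain <- function(y, X, mi, mj, M, w, prior, iter, warmup, seed) {
  set.seed(seed)
  n <- length(y); p <- ncol(X)
  XtX <- crossprod(X)
  ## Z'Z and X'Z for the multi-membership design (each dyad loads w on both
  ## of its members)
  ZtZ <- matrix(0, M, M)
  for (k in seq_len(n)) {
    ZtZ[mi[k], mi[k]] <- ZtZ[mi[k], mi[k]] + w^2
    ZtZ[mj[k], mj[k]] <- ZtZ[mj[k], mj[k]] + w^2
    ZtZ[mi[k], mj[k]] <- ZtZ[mi[k], mj[k]] + w^2
    ZtZ[mj[k], mi[k]] <- ZtZ[mj[k], mi[k]] + w^2
  }
  acc_members <- function(v) {
    a <- matrix(0, M, ncol(v))
    s1 <- rowsum(v, mi); a[as.integer(rownames(s1)), ] <- s1
    s2 <- rowsum(v, mj)
    a[as.integer(rownames(s2)), ] <- a[as.integer(rownames(s2)), ] + s2
    w * a
  }
  XtZ <- t(acc_members(X))
  Zty <- drop(acc_members(matrix(y)))
  q <- p + M
  WtW <- rbind(cbind(XtX, XtZ), cbind(t(XtZ), ZtZ))
  Wty <- c(drop(crossprod(X, y)), Zty)
  prior_prec <- c(rep(1 / prior$sd_beta^2, p), rep(NA_real_, M))

  ## mildly overdispersed, chain-specific initial values
  s2 <- stats::var(y) * stats::runif(1L, 0.5, 2)
  if (!is.finite(s2) || s2 <= 0) s2 <- 1
  s2u <- s2 * stats::runif(1L, 0.1, 1)
  a_e <- a_u <- 1
  nu <- prior$nu
  A_e <- prior$scale_sigma; A_u <- prior$scale_sigma_u

  keep <- iter - warmup
  draws <- matrix(NA_real_, keep, p + 2L)
  u_sum <- numeric(M)

  for (it in seq_len(iter)) {
    ## joint (beta, u) block
    Q <- WtW / s2
    dg <- prior_prec; dg[(p + 1L):q] <- 1 / s2u
    diag(Q) <- diag(Q) + dg
    R <- chol(Q)
    tmean <- backsolve(R, backsolve(R, Wty / s2, transpose = TRUE))
    theta <- drop(tmean + backsolve(R, stats::rnorm(q)))
    beta <- theta[seq_len(p)]
    u <- theta[(p + 1L):q]
    ## variance components (Huang-Wand half-t)
    ssr <- sum((y - drop(X %*% beta) - w * (u[mi] + u[mj]))^2)
    ## variance floor: degenerate responses that the member effects fit
    ## exactly would otherwise drive s2 to numerical zero and overflow Q
    s2 <- max(.rinvgamma1((nu + n) / 2, nu / a_e + ssr / 2), 1e-12)
    a_e <- .rinvgamma1((nu + 1) / 2, nu / s2 + 1 / A_e^2)
    s2u <- max(.rinvgamma1((nu + M) / 2, nu / a_u + sum(u^2) / 2), 1e-12)
    a_u <- .rinvgamma1((nu + 1) / 2, nu / s2u + 1 / A_u^2)

    if (it > warmup) {
      k <- it - warmup
      draws[k, ] <- c(beta, sqrt(s2u), sqrt(s2))
      u_sum <- u_sum + u
    }
  }
  list(draws = draws, u_mean = u_sum / keep)
}

#' Fit a Bayesian multi-membership dyadic regression
#'
#' Models a pairwise community-similarity response over all dyads of samples
#' as a Gaussian linear function of dyad-level predictors, with a
#' multi-membership random intercept: each dyad inherits the random effects of
#' both of its members,
#' \deqn{y_{ij} = \alpha + \sum_k \beta_k x_k(ij) + u_i + u_j + \epsilon_{ij},}
#' with \eqn{u \sim N(0, \sigma_u^2)} shared across both membership positions
#' and \eqn{\epsilon \sim N(0, \sigma^2)}. Because dyads sharing a member are
#' not independent, the member effects absorb individual-level signal that
#' would otherwise make fixed-effect credible intervals anti-conservative.
#'
#' The posterior is sampled by an exact blocked Gibbs sampler (all full
#' conditionals are conjugate under the [dyad_mm_prior()] priors), run over
#' several independent chains with overdispersed initial values. Convergence
#' is assessed by rank-normalized split-\eqn{\widehat{R}}.
#'
#' @param formula Model formula on the dyad table, e.g.
#'   `similarity_jaccard ~ spatial_dist_sc + gen_dist_sc * hhe_dist_sc`.
#' @param data A [build_dyads()] table (any data frame with the two member
#'   columns works).
#' @param members Character vector of length 2 naming the member-id columns;
#'   defaults to `ind_i`/`ind_j` when present, else `member_i`/`member_j`.
#' @param chains Number of independent chains (>= 2 for convergence checks).
#' @param iter Total iterations per chain.
#' @param warmup Burn-in iterations discarded per chain.
#' @param seed Master seed; per-chain seeds are derived from it
#'   deterministically.
#' @param prior A [dyad_mm_prior()] list.
#' @param member_weight Loading of each member's random effect on the dyad
#'   (default 1: the dyad receives the sum `u_i + u_j`; 0.5 gives the mean).
#' @param standardize_response Optional: z-standardize the response before
#'   fitting (coefficients are then on response-SD scale).
#' @return Object of class `dyad_mm` with posterior draws; see
#'   [summary.dyad_mm()].
#' @export
dyad_mm <- function(formula, data, members = NULL, chains = 4, iter = 3000,
                    warmup = 1000, seed = 1, prior = dyad_mm_prior(),
                    member_weight = 1, standardize_response = FALSE) {
  stopifnot(chains >= 2, warmup < iter)
  if (is.null(members)) {
    members <- if (all(c("ind_i", "ind_j") %in% names(data))) {
      c("ind_i", "ind_j")
    } else c("member_i", "member_j")
  }
  if (!all(members %in% names(data))) {
    stop("member columns not found in `data`: ",
         paste(setdiff(members, names(data)), collapse = ", "))
  }
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (stats::var(y) == 0) {
    stop("constant response: every dyad has the same similarity; ",
         "the model variances are not identifiable from such data")
  }
  if (standardize_response) y <- as.numeric(scale(y))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  ## collinearity check
  sv <- svd(scale(X[, -1L, drop = FALSE], scale = FALSE))$d
  if (length(sv) > 1L && sv[length(sv)] > 0 &&
      sv[1L] / sv[length(sv)] > 1e6) {
    warning("near-singular dyad design; condition number ",
            format(sv[1L] / sv[length(sv)], digits = 3))
  }
  ids <- sort(unique(c(as.character(data[[members[1L]]]),
                       as.character(data[[members[2L]]]))))
  mi <- match(as.character(data[[members[1L]]]), ids)
  mj <- match(as.character(data[[members[2L]]]), ids)

  set.seed(seed)
  chain_seeds <- sample.int(2147483646L, chains)
  fits <- lapply(seq_len(chains), function(c) {
    .gibbs_chain(y, X, mi, mj, length(ids), member_weight, prior,
                 iter, warmup, chain_seeds[c])
  })
  keep <- iter - warmup
  par_names <- c(colnames(X), "sigma_u", "sigma")
  draws <- array(NA_real_, c(keep, chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (c in seq_len(chains)) draws[, c, ] <- fits[[c]]$draws
  u_mean <- Reduce(`+`, lapply(fits, `[[`, "u_mean")) / chains

  structure(
    list(draws = draws, par_names = par_names,
         fixed_names = colnames(X),
         u_mean = stats::setNames(u_mean, ids),
         y = y, X = X, mi = mi, mj = mj, member_ids = ids,
         members = members, member_weight = member_weight,
         formula = formula, chains = chains, iter = iter, warmup = warmup,
         seed = seed, prior = prior, call = match.call()),
    class = "dyad_mm"
  )
}

## rank-normalized split-R-hat (bulk, and folded for tails); max of the two
rhat_rank <- function(draws) {
  ## draws: iterations x chains matrix
  split_rhat <- function(m) {
    S <- nrow(m); C <- ncol(m)
    h <- floor(S / 2)
    sm <- cbind(m[seq_len(h), , drop = FALSE],
                m[(S - h + 1):S, , drop = FALSE])
    r <- matrix(rank(sm, ties.method = "average"), nrow = h)
    z <- stats::qnorm((r - 3 / 8) / (length(sm) + 1 / 4))
    n <- nrow(z)
    mns <- colMeans(z)
    W <- mean(apply(z, 2L, stats::var))
    B <- n * stats::var(mns)
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  bulk <- split_rhat(draws)
  folded <- split_rhat(abs(draws - stats::median(draws)))
  max(bulk, folded)
}

#' Summarize a fitted dyadic model
#'
#' Per parameter (all fixed effects plus `sigma_u` and `sigma`): posterior
#' mean, SD, 95% credible interval (2.5% and 97.5% quantiles),
#' rank-normalized split-\eqn{\widehat{R}}, a `significant` flag (the CI
#' excludes 0; only meaningful for coefficients) and a `reliable` flag
#' (\eqn{\widehat{R} \le} `rhat_reliable`). If any parameter exceeds
#' `rhat_fail` the summary carries `converged = FALSE` and a warning is
#' emitted — results are flagged, never suppressed.
#'
#' @param object A [dyad_mm] fit.
#' @param prob Credible-interval mass (default 0.95).
#' @param rhat_reliable Reliability threshold (default 1.01).
#' @param rhat_fail Hard convergence-failure threshold (default 1.05).
#' @param ... Unused.
#' @return Data frame of class `summary.dyad_mm`, one row per parameter, with
#'   attributes `converged`, `nobs`, `n_members`.
#' @export
summary.dyad_mm <- function(object, prob = 0.95, rhat_reliable = 1.01,
                            rhat_fail = 1.05, ...) {
  a <- (1 - prob) / 2
  tab <- do.call(rbind, lapply(object$par_names, function(pn) {
    d <- object$draws[, , pn]
    q <- stats::quantile(d, c(a, 1 - a), names = FALSE)
    data.frame(parameter = pn, estimate = mean(d), sd = stats::sd(d),
               ci_lower = q[1L], ci_upper = q[2L],
               rhat = rhat_rank(as.matrix(d)), stringsAsFactors = FALSE)
  }))
  tab$significant <- tab$ci_lower > 0 | tab$ci_upper < 0
  tab$significant[tab$parameter %in% c("sigma_u", "sigma")] <- NA
  tab$reliable <- tab$rhat <= rhat_reliable
  rownames(tab) <- NULL
  converged <- all(tab$rhat <= rhat_fail)
  if (!converged) {
    warning("convergence failure: R-hat > ", rhat_fail, " for ",
            paste(tab$parameter[tab$rhat > rhat_fail], collapse = ", "))
  }
  structure(tab, class = c("summary.dyad_mm", "data.frame"),
            converged = converged, nobs = length(object$y),
            n_members = length(object$member_ids), prob = prob)
}

#' @export
print.summary.dyad_mm <- function(x, digits = 3, ...) {
  cat("Bayesian multi-membership dyadic regression\n")
  cat(attr(x, "nobs"), "dyads over", attr(x, "n_members"), "members\n\n")
  df <- as.data.frame(x)
  df$estimate <- round(df$estimate, digits)
  df$sd <- round(df$sd, digits)
  df$ci_lower <- round(df$ci_lower, digits)
  df$ci_upper <- round(df$ci_upper, digits)
  df$rhat <- round(df$rhat, max(digits, 2))
  print.data.frame(df, row.names = FALSE)
  if (!attr(x, "converged")) cat("\nWARNING: convergence failure flagged\n")
  invisible(x)
}

#' @export
print.dyad_mm <- function(x, ...) {
  cat("dyad_mm fit:", deparse(x$formula), "\n")
  cat("  ", length(x$y), "dyads,", length(x$member_ids), "members,",
      x$chains, "chains x", x$iter, "iterations (", x$warmup, "warmup )\n")
  est <- apply(x$draws, 3L, mean)
  print(round(est, 3))
  invisible(x)
}

#' @export
coef.dyad_mm <- function(object, ...) {
  est <- apply(object$draws[, , object$fixed_names, drop = FALSE], 3L, mean)
  stats::setNames(est, object$fixed_names)
}

#' Posterior means of the member random effects
#' @param object A [dyad_mm] fit.
#' @param ... Unused.
#' @return Named numeric vector, one entry per member.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @rdname ranef
#' @export
ranef.dyad_mm <- function(object, ...) object$u_mean

#' @export
fitted.dyad_mm <- function(object, ...) {
  drop(object$X %*% coef(object)) +
    object$member_weight * (object$u_mean[object$mi] + object$u_mean[object$mj])
}

#' @export
residuals.dyad_mm <- function(object, ...) object$y - fitted(object)

#' Predict from a fitted dyadic model
#'
#' @param object A [dyad_mm] fit.
#' @param newdata Optional data frame with the predictor (and, for
#'   `re_form = "member"`, member-id) columns; defaults to the training data
#'   design.
#' @param re_form `"none"` (fixed effects only) or `"member"` (add posterior
#'   mean random effects of known members; unknown members get 0).
#' @param ... Unused.
#' @return Numeric vector of posterior-mean predictions.
#' @export
predict.dyad_mm <- function(object, newdata = NULL, re_form = c("none", "member"),
                            ...) {
  re_form <- match.arg(re_form)
  if (is.null(newdata)) {
    X <- object$X
    ui <- object$u_mean[object$mi]; uj <- object$u_mean[object$mj]
  } else {
    tt <- stats::delete.response(stats::terms(object$formula))
    X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
    u <- function(col) {
      v <- object$u_mean[as.character(newdata[[col]])]
      ifelse(is.na(v), 0, v)
    }
    ui <- if (object$members[1L] %in% names(newdata)) u(object$members[1L]) else 0
    uj <- if (object$members[2L] %in% names(newdata)) u(object$members[2L]) else 0
  }
  out <- drop(X %*% coef(object))
  if (re_form == "member") out <- out + object$member_weight * (ui + uj)
  unname(out)
}

#' Simulate from the posterior predictive distribution
#'
#' Draws replicate dyad responses: for each simulation a posterior draw
#' (beta, sigma_u, sigma) is selected at random and a new response vector is
#' generated from the model, marginalizing over the member effects (fresh
#' `u` are drawn for the members).
#'
#' @param object A [dyad_mm] fit.
#' @param nsim Number of replicate response vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns, one simulated response per column.
#' @export
simulate.dyad_mm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$draws
  flat <- matrix(d, prod(dim(d)[1:2]), dim(d)[3L],
                 dimnames = list(NULL, object$par_names))
  M <- length(object$member_ids)
  out <- replicate(nsim, {
    row <- flat[sample.int(nrow(flat), 1L), ]
    beta <- row[object$fixed_names]
    u <- stats::rnorm(M, 0, row["sigma_u"])
    drop(object$X %*% beta) +
      object$member_weight * (u[object$mi] + u[object$mj]) +
      stats::rnorm(length(object$y), 0, row["sigma"])
  })
  as.data.frame(out)
}

#' Forest / trace plot of a fitted dyadic model
#'
#' `type = "forest"` draws posterior means and 95% credible intervals of the
#' coefficients (excluding the intercept by default), the standard display for
#' dyadic-model effect comparisons; `type = "trace"` draws per-chain traces
#' for each parameter.
#'
#' @param x A [dyad_mm] fit.
#' @param type `"forest"` or `"trace"`.
#' @param include_intercept Include the intercept row in the forest plot.
#' @param ... Passed to the underlying plotting calls.
#' @return `x`, invisibly.
#' @export
plot.dyad_mm <- function(x, type = c("forest", "trace"),
                         include_intercept = FALSE, ...) {
  type <- match.arg(type)
  if (type == "forest") {
    s <- summary(x)
    s <- s[!s$parameter %in% c("sigma", "sigma_u"), , drop = FALSE]
    if (!include_intercept) {
      s <- s[s$parameter != "(Intercept)", , drop = FALSE]
    }
    k <- nrow(s)
    graphics::plot(s$estimate, seq_len(k), xlim = range(s$ci_lower, s$ci_upper, 0),
                   ylim = c(0.5, k + 0.5), yaxt = "n", pch = 16,
                   xlab = "standardized effect on similarity", ylab = "", ...)
    graphics::segments(s$ci_lower, seq_len(k), s$ci_upper, seq_len(k))
    graphics::abline(v = 0, lty = 2, col = "grey50")
    graphics::axis(2, at = seq_len(k), labels = s$parameter, las = 1, cex.axis = 0.8)
  } else {
    old <- graphics::par(mfrow = c(ceiling(length(x$par_names) / 2), 2),
                         mar = c(2, 4, 1, 1))
    on.exit(graphics::par(old))
    for (pn in x$par_names) {
      graphics::matplot(x$draws[, , pn], type = "l", lty = 1, ylab = pn, ...)
    }
  }
  invisible(x)
}
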