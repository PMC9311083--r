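#' Sampling (co)variance matrix of a set of effect sizes
#'
#' Block-diagonal-by-experiment matrix `M` with each effect's sampling
#' variance `V` on the diagonal and, between effects from the same
#' experiment, the covariance `cov_ij = r * sqrt(V_i * V_j)` that accounts
#' for their non-independence. Zero covariance across experiments.
#'
#' @param effects Effects tibble (needs columns `V`, `study_id`,
#'   `experiment_id`).
#' @param r Assumed correlation between effect sizes within an experiment
#'   (default 0.5).
#' @return A dense symmetric positive semi-definite `n x n` matrix.
#' @examples
#' eff <- tibble::tibble(study_id = "s", experiment_id = "e",
#'                       V = c(0.04, 0.09))
#' build_M(eff) # off-diagonal 0.5 * 0.2 * 0.3 = 0.03
#' @export
build_M <- function(effects, r = 0.5) {
  if (any(effects$V <= 0)) stop("sampling variances must be positive", call. = FALSE)
  if (abs(r) >= 1) stop("'r' must have |r| < 1", call. = FALSE)
  n <- nrow(effects)
  se <- sqrt(effects$V)
  blk <- interaction(effects$study_id, effects$experiment_id, drop = TRUE)
  same <- outer(blk, blk, "==")
  M <- r * tcrossprod(se) * same
  diag(M) <- effects$V
  M
}

#' MCMC configuration for the meta-regression sampler
#'
#' @param n_iter Iterations per chain (including burn-in).
#' @param burn_in Discarded iterations per chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param n_chains Number of chains (seeded `seed + chain - 1`).
#' @param seed Base RNG seed.
#' @param prior_shape,prior_rate Inverse-gamma prior on every variance
#'   component (shape 0.001, rate 0.001 by default: scaled to be weakly
#'   informative).
#' @param random Random-effect components to include, a subset of
#'   `c("species", "phylogeny", "study", "experiment")`.
#' @param fix_residual Optional named vector `c(F = , M = )` of residual
#'   variances to hold fixed instead of sampling (used for validation
#'   against conjugate closed forms).
#' @param r_within Within-experiment sampling correlation passed to
#'   [build_M()].
#' @return A `meta_config` list.
#' @export
meta_config <- function(n_iter = 30000L, burn_in = 10000L, thin = 10L,
                        n_chains = 4L, seed = 42L,
                        prior_shape = 0.001, prior_rate = 0.001,
                        random = c("species", "phylogeny", "study", "experiment"),
                        fix_residual = NULL, r_within = 0.5) {
  if (n_iter <= burn_in) stop("need n_iter > burn_in", call. = FALSE)
  if (length(random))
    random <- match.arg(random, several.ok = TRUE)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed), prior_shape = prior_shape,
                 prior_rate = prior_rate, random = random,
                 fix_residual = fix_residual, r_within = r_within),
            class = "meta_config")
}

norm_species <- function(x) tolower(gsub("[ _]+", "_", trimws(x)))

# design matrix with aliased columns dropped
build_design <- function(effects, moderator = NULL, extra = NULL) {
  df <- data.frame(row.names = seq_len(nrow(effects)))
  has_sex <- "sex" %in% names(effects) &&
    length(unique(stats::na.omit(effects$sex))) > 1
  form <- "~ 1"
  if (has_sex) {
    df$sex <- factor(effects$sex, levels = c("F", "M"))
    form <- "~ sex"
  }
  if (!is.null(moderator)) {
    mod <- droplevels(factor(effects[[moderator]]))
    if (nlevels(mod) < 2) {
      warning("moderator has a single level: unestimable, dropped",
              call. = FALSE)
    } else {
      df$moderator <- mod
      form <- if (has_sex) "~ sex * moderator" else "~ moderator"
    }
  }
  if (!is.null(extra)) {
    df[[names(extra)]] <- extra[[1]]
    form <- paste(form, "+", names(extra))
  }
  X <- stats::model.matrix(stats::as.formula(form), df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    warning("dropping unestimable design columns: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

# --- the Gibbs sampler -----------------------------------------------------

# Partition the experiment blocks of M by size. Sizes 1 and 2 (the common
# cases) get closed-form solves vectorised across blocks; larger blocks are
# handled individually.
index_blocks <- function(M, blk_id) {
  n <- nrow(M)
  idx <- split(seq_len(n), blk_id)
  sizes <- lengths(idx)
  i1 <- unlist(idx[sizes == 1L], use.names = FALSE)
  pairs <- idx[sizes == 2L]
  p1 <- vapply(pairs, `[`, integer(1), 1L)
  p2 <- vapply(pairs, `[`, integer(1), 2L)
  big <- lapply(idx[sizes > 2L], function(i) {
    Mb <- M[i, i, drop = FALSE]
    list(i = i, M = Mb, Minv = chol2inv(chol(Mb)))
  })
  M11 <- M[cbind(p1, p1)]; M22 <- M[cbind(p2, p2)]; M12 <- M[cbind(p1, p2)]
  detM <- M11 * M22 - M12^2
  list(
    s1 = list(i = i1, V = diag(M)[i1]),
    s2 = list(i1 = p1, i2 = p2, M11 = M11, M22 = M22, M12 = M12,
              I11 = M22 / detM, I22 = M11 / detM, I12 = -M12 / detM),
    big = big
  )
}

# One chain. Location effects (beta, m) are drawn as a block: beta from its
# conditional with the known-sampling-error vector m integrated out
# (precision X' (D + M)^-1 X), then m | beta. Random effects and variance
# components are standard conjugate updates. All per-experiment solves are
# done blockwise on the small M blocks.
run_chain <- function(y, X, Mblocks, groups, Ainv, cfg, chain_seed) {
  set.seed(chain_seed)
  n <- length(y)
  p <- ncol(X)
  a0 <- cfg$prior_shape
  b0 <- cfg$prior_rate
  comps <- cfg$random
  sexF <- groups$sexF # logical: residual stratum F

  # group index vectors (integer) and level counts
  idx <- groups$idx
  nlev <- vapply(idx, function(i) max(i), integer(1))

  beta <- rep(0, p)
  m <- rep(0, n)
  u <- lapply(nlev, function(q) rep(0, q))
  s2 <- stats::setNames(rep(0.1, length(comps)), comps)
  fixed_res <- !is.null(cfg$fix_residual)
  s2res <- if (fixed_res) c(F = unname(cfg$fix_residual["F"]),
                            M = unname(cfg$fix_residual["M"]))
  else c(F = stats::var(y) / 2 + 1e-6, M = stats::var(y) / 2 + 1e-6)

  keep <- seq(cfg$burn_in + cfg$thin, cfg$n_iter, by = cfg$thin)
  draws <- matrix(NA_real_, length(keep),
                  p + length(comps) + 2,
                  dimnames = list(NULL, c(colnames(X),
                                          if (length(comps)) paste0("sigma2_", comps),
                                          "sigma2_resid_F", "sigma2_resid_M")))
  k_out <- 0L

  zu_total <- function() {
    tot <- rep(0, n)
    for (k in seq_along(comps)) tot <- tot + u[[k]][idx[[k]]]
    tot
  }

  for (it in seq_len(cfg$n_iter)) {
    d <- ifelse(sexF, s2res[["F"]], s2res[["M"]])
    zu <- zu_total()

    # (beta, m) block: beta | u, sigma  (m marginalised), then m | beta, u
    resid0 <- y - zu
    G <- matrix(0, p, p + 1)            # accumulates X' R^-1 [X, resid0]
    bs1 <- Mblocks$s1; bs2 <- Mblocks$s2
    if (length(bs1$i)) {
      ri <- 1 / (bs1$V + d[bs1$i])
      Z <- cbind(X[bs1$i, , drop = FALSE], resid0[bs1$i])
      G <- G + crossprod(X[bs1$i, , drop = FALSE], Z * ri)
    }
    if (length(bs2$i1)) {
      a <- bs2$M11 + d[bs2$i1]; bb2 <- bs2$M22 + d[bs2$i2]; cc <- bs2$M12
      det <- a * bb2 - cc^2
      Z1 <- cbind(X[bs2$i1, , drop = FALSE], resid0[bs2$i1])
      Z2 <- cbind(X[bs2$i2, , drop = FALSE], resid0[bs2$i2])
      W1 <- (Z1 * bb2 - Z2 * cc) / det
      W2 <- (Z2 * a - Z1 * cc) / det
      G <- G + crossprod(X[bs2$i1, , drop = FALSE], W1) +
        crossprod(X[bs2$i2, , drop = FALSE], W2)
    }
    for (b in Mblocks$big) {
      Rb <- b$M
      diag(Rb) <- diag(Rb) + d[b$i]
      sol <- solve(Rb, cbind(X[b$i, , drop = FALSE], resid0[b$i]))
      G <- G + crossprod(X[b$i, , drop = FALSE], sol)
    }
    ch <- chol(G[, 1:p, drop = FALSE])
    beta <- backsolve(ch, backsolve(ch, G[, p + 1], transpose = TRUE)) +
      backsolve(ch, stats::rnorm(p))

    e_for_m <- resid0 - as.vector(X %*% beta)
    if (length(bs1$i)) {
      prec <- 1 / bs1$V + 1 / d[bs1$i]
      m[bs1$i] <- (e_for_m[bs1$i] / d[bs1$i]) / prec +
        stats::rnorm(length(bs1$i)) / sqrt(prec)
    }
    if (length(bs2$i1)) {
      P11 <- bs2$I11 + 1 / d[bs2$i1]; P22 <- bs2$I22 + 1 / d[bs2$i2]; P12 <- bs2$I12
      detP <- P11 * P22 - P12^2
      r1 <- e_for_m[bs2$i1] / d[bs2$i1]; r2 <- e_for_m[bs2$i2] / d[bs2$i2]
      mu1 <- (P22 * r1 - P12 * r2) / detP
      mu2 <- (P11 * r2 - P12 * r1) / detP
      s11 <- P22 / detP; s22 <- P11 / detP; s12 <- -P12 / detP
      z1 <- stats::rnorm(length(mu1)); z2 <- stats::rnorm(length(mu2))
      m[bs2$i1] <- mu1 + sqrt(s11) * z1
      m[bs2$i2] <- mu2 + (s12 / sqrt(s11)) * z1 +
        sqrt(pmax(s22 - s12^2 / s11, 0)) * z2
    }
    for (b in Mblocks$big) {
      P <- b$Minv
      diag(P) <- diag(P) + 1 / d[b$i]
      cp <- chol(P)
      mean_b <- backsolve(cp, backsolve(cp, e_for_m[b$i] / d[b$i],
                                        transpose = TRUE))
      m[b$i] <- mean_b + backsolve(cp, stats::rnorm(length(b$i)))
    }

    # random effects
    base <- y - as.vector(X %*% beta) - m
    for (k in seq_along(comps)) {
      others <- rep(0, n)
      for (j in seq_along(comps)) if (j != k) others <- others + u[[j]][idx[[j]]]
      r_k <- base - others
      g <- idx[[k]]
      h <- as.vector(rowsum(1 / d, g))            # sum of precisions per level
      bb <- as.vector(rowsum(r_k / d, g))
      if (comps[k] == "phylogeny") {
        P <- Ainv / s2[k]
        diag(P) <- diag(P) + h
        cp <- chol(P)
        u[[k]] <- as.vector(backsolve(cp, backsolve(cp, bb, transpose = TRUE)) +
                              backsolve(cp, stats::rnorm(length(bb))))
        quad <- as.numeric(crossprod(u[[k]], Ainv %*% u[[k]]))
      } else {
        prec <- h + 1 / s2[k]
        u[[k]] <- stats::rnorm(length(bb), bb / prec, sqrt(1 / prec))
        quad <- sum(u[[k]]^2)
      }
      s2[k] <- 1 / stats::rgamma(1, a0 + nlev[k] / 2, b0 + quad / 2)
    }

    # sex-specific residual variances
    if (!fixed_res) {
      e <- base - zu_total()
      for (s in c("F", "M")) {
        sel <- if (s == "F") sexF else !sexF
        if (any(sel))
          s2res[[s]] <- 1 / stats::rgamma(1, a0 + sum(sel) / 2,
                                          b0 + sum(e[sel]^2) / 2)
      }
    }

    if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0) {
      k_out <- k_out + 1L
      draws[k_out, ] <- c(beta, if (length(comps)) s2, s2res)
    }
  }
  draws
}

split_rhat <- function(chain_list) {
  # split each chain in half, compute potential scale reduction factor
  halves <- unlist(lapply(chain_list, function(x) {
    h <- floor(length(x) / 2)
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  # sum of autocorrelations until first negative (initial positive sequence)
  pos <- which(ac < 0)
  upto <- if (length(pos)) pos[1] - 1 else length(ac)
  tau <- 1 + 2 * sum(ac[seq_len(upto)])
  n / max(tau, 1)
}

#' Bayesian phylogenetic multilevel meta-regression
#'
#' Fits, by blocked Gibbs sampling, the model
#' `y = X beta + u_species + u_phylogeny + u_study + u_experiment + m + e`,
#' where `m` has the known sampling covariance `M` (effect sampling
#' variances on the diagonal, within-experiment correlation `r_within`),
#' `u_phylogeny ~ N(0, sigma2_ph * A)` for the Grafen correlation matrix
#' `A`, the other random effects are i.i.d. normal, and the residual `e`
#' has a sex-specific variance. Fixed effects default to an intercept (the
#' female mean effect) plus the sex(male) deviation. Effects are thereby
#' weighted by their sampling error variance, with phylogeny and species as
#' separate components.
#'
#' @param effects Effects tibble (from [compute_effects()]); needs `value`,
#'   `V`, `sex`, `species`, `study_id`, `experiment_id`.
#' @param A_phylo Phylogenetic correlation matrix from
#'   [grafen_correlation()]; required when `"phylogeny"` is in
#'   `config$random`.
#' @param config A [meta_config()].
#' @param moderator Optional name of a categorical column in `effects` to
#'   cross with sex (see [fit_moderators()]).
#' @param extra_fixed Optional single-column named list of a continuous
#'   fixed covariate (used by [publication_bias()]).
#' @param force Report even if any split R-hat exceeds 1.1 (otherwise an
#'   error).
#' @return A `meta_fit` object: `draws` (matrix of posterior draws pooled
#'   over chains), `summary` (tibble of posterior means and 95\% credible
#'   intervals), `diagnostics` (R-hat, effective sample size), plus the
#'   design and data needed by downstream summaries.
#' @export
fit_meta <- function(effects, A_phylo = NULL, config = meta_config(),
                     moderator = NULL, extra_fixed = NULL, force = FALSE) {
  stopifnot(inherits(config, "meta_config"))
  n <- nrow(effects)
  if (n < 2) stop("need at least two effect sizes", call. = FALSE)
  if (any(!is.finite(effects$value))) stop("non-finite effect values", call. = FALSE)
  y <- effects$value
  X <- build_design(effects, moderator = moderator, extra = extra_fixed)

  M <- build_M(effects, r = config$r_within)
  blk_id <- interaction(effects$study_id, effects$experiment_id, drop = TRUE)
  Mblocks <- index_blocks(M, blk_id)

  comps <- config$random
  idx <- list()
  Ainv <- NULL
  sp <- norm_species(effects$species)
  if ("species" %in% comps)
    idx$species <- as.integer(factor(sp))
  if ("phylogeny" %in% comps) {
    if (is.null(A_phylo)) stop("'A_phylo' required for the phylogeny component",
                               call. = FALSE)
    rownames(A_phylo) <- colnames(A_phylo) <- norm_species(rownames(A_phylo))
    spl <- sort(unique(sp))
    miss <- setdiff(spl, rownames(A_phylo))
    if (length(miss)) stop("species missing from A_phylo: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    A <- A_phylo[spl, spl, drop = FALSE]
    ev <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) stop("A_phylo is not positive semi-definite", call. = FALSE)
    Ainv <- chol2inv(chol(A + diag(1e-10, nrow(A))))
    idx$phylogeny <- match(sp, spl)
  }
  if ("study" %in% comps)
    idx$study <- as.integer(factor(effects$study_id))
  if ("experiment" %in% comps)
    idx$experiment <- as.integer(blk_id)
  idx <- idx[comps]

  sexF <- if ("sex" %in% names(effects)) !effects$sex %in% "M" else rep(TRUE, n)
  groups <- list(idx = idx, sexF = sexF)

  chains <- lapply(seq_len(config$n_chains), function(ch)
    run_chain(y, X, Mblocks, groups, Ainv, config, config$seed + ch - 1L))

  draws <- do.call(rbind, chains)
  pars <- colnames(draws)
  rhat <- vapply(pars, function(pp)
    split_rhat(lapply(chains, function(cc) cc[, pp])), numeric(1))
  ess <- vapply(pars, function(pp) sum(vapply(chains, function(cc)
    ess_basic(cc[, pp]), numeric(1))), numeric(1))

  if (!force && any(rhat > 1.1, na.rm = TRUE))
    stop("chains have not converged (max split R-hat = ",
         sprintf("%.3f", max(rhat, na.rm = TRUE)),
         "); increase n_iter or pass force = TRUE", call. = FALSE)

  qs <- t(apply(draws, 2, stats::quantile, c(0.025, 0.975)))
  summ <- tibble::tibble(
    parameter = pars,
    mean = unname(colMeans(draws)),
    lower95 = unname(qs[, 1]), upper95 = unname(qs[, 2]),
    rhat = unname(rhat), ess = unname(ess)
  )
  structure(list(draws = draws, summary = summ,
                 diagnostics = list(rhat = rhat, ess = ess),
                 X = X, effects = effects, config = config,
                 fixed_names = colnames(X),
                 random = comps),
            class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf("Multilevel meta-regression: %d effects, %d chains x %d draws\n",
              nrow(x$effects), x$config$n_chains,
              nrow(x$draws) / x$config$n_chains))
  print(as.data.frame(x$summary), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Expected magnitude of a folded-normal variable
#'
#' Closed-form mean of `|X|` for `X ~ Normal(mu, sigma^2)`:
#' `E|X| = sigma*sqrt(2/pi)*exp(-mu^2/(2 sigma^2)) + mu*(1 - 2*pnorm(-mu/sigma))`.
#'
#' @param mu,sigma Mean and standard deviation of the underlying normal
#'   (`sigma > 0`); vectorised.
#' @return `E|X|`.
#' @examples
#' folded_normal_mean(0, 1) # sqrt(2/pi)
#' @export
folded_normal_mean <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("'sigma' must be positive", call. = FALSE)
  sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) +
    mu * (1 - 2 * stats::pnorm(-mu / sigma))
}

#' Posterior magnitude of the mean effect (analyse-then-transform)
#'
#' Summarises `|d|` from a Gaussian meta-regression fit by applying the
#' folded-normal mean to each posterior draw: `mu` is the sex-specific mean
#' (intercept, plus the sex(male) deviation for males) and `sigma^2` is
#' either the sum of all heterogeneity variance components plus that sex's
#' residual variance (`sigma = "total"`, the default) or the sex-specific
#' residual variance alone (`"residual_only"`).
#'
#' @param fit A `meta_fit` object.
#' @param sex `"F"` or `"M"`.
#' @param sigma Which heterogeneity variances spread the folded normal.
#' @return Tibble with the posterior mean and 95\% credible interval of
#'   `|d|`.
#' @export
folded_mean <- function(fit, sex = c("F", "M"),
                        sigma = c("total", "residual_only")) {
  stopifnot(inherits(fit, "meta_fit"))
  sex <- match.arg(sex)
  sigma <- match.arg(sigma)
  dr <- fit$draws
  mu <- dr[, fit$fixed_names[1]]
  if (sex == "M" && "sexM" %in% colnames(dr)) mu <- mu + dr[, "sexM"]
  res_col <- paste0("sigma2_resid_", sex)
  s2 <- dr[, res_col]
  if (sigma == "total")
    for (cc in fit$random) s2 <- s2 + dr[, paste0("sigma2_", cc)]
  if (any(s2 <= 0)) stop("non-positive variance draw", call. = FALSE)
  vals <- folded_normal_mean(mu, sqrt(s2))
  tibble::tibble(sex = sex, mean = mean(vals),
                 lower95 = unname(stats::quantile(vals, 0.025)),
                 upper95 = unname(stats::quantile(vals, 0.975)))
}

#' Heterogeneity partition and variance explained
#'
#' Partitions effect-size heterogeneity into I-squared components, one per
#' variance component plus the residual:
#' `I2_k = sigma2_k / (sum_k sigma2_k + sigma2_typical)`, with the typical
#' sampling variance given by the weight-based formula
#' `s2_typ = sum(w) * (k - 1) / (sum(w)^2 - sum(w^2))`, `w = 1/V` (or the
#' mean sampling variance when `typical = "mean"`). The component values sum
#' to the total by construction. Also returns marginal (fixed-effects-only)
#' and conditional (fixed + random) R-squared computed per posterior draw
#' from the variance of the fitted fixed values.
#'
#' @param fit A `meta_fit` object.
#' @param effects Effects tibble supplying the sampling variances `V`
#'   (defaults to the table the model was fitted to).
#' @param typical `"higgins"` (weight-based, default) or `"mean"`.
#' @return A list with `I2` (tibble of percentages per component and total)
#'   and `R2` (marginal, conditional).
#' @export
heterogeneity <- function(fit, effects = fit$effects,
                          typical = c("higgins", "mean")) {
  stopifnot(inherits(fit, "meta_fit"))
  typical <- match.arg(typical)
  w <- 1 / effects$V
  k <- length(w)
  s2_typ <- if (typical == "higgins") sum(w) * (k - 1) / (sum(w)^2 - sum(w^2))
  else mean(effects$V)

  dr <- fit$draws
  comp_names <- c(fit$random, "residual")
  nF <- sum(fit$effects$sex %in% c("F", NA)) # residual strata sizes
  nM <- nrow(fit$effects) - nF
  resid_draw <- (dr[, "sigma2_resid_F"] * nF + dr[, "sigma2_resid_M"] * nM) /
    (nF + nM)
  comp_draws <- cbind(
    if (length(fit$random))
      dr[, paste0("sigma2_", fit$random), drop = FALSE],
    residual = resid_draw)
  sig2 <- colMeans(comp_draws)
  names(sig2) <- comp_names
  tot <- sum(sig2)
  I2 <- 100 * sig2 / (tot + s2_typ)
  I2_tbl <- tibble::tibble(component = c(comp_names, "total"),
                           I2 = unname(c(I2, sum(I2))))

  Xb <- fit$X %*% t(dr[, fit$fixed_names, drop = FALSE])
  var_fix <- apply(Xb, 2, stats::var)
  rand_sum <- rowSums(comp_draws) - comp_draws[, "residual"]
  denom <- var_fix + rowSums(comp_draws)
  R2m <- mean(var_fix / denom)
  R2c <- mean((var_fix + rand_sum) / denom)
  list(I2 = I2_tbl, R2 = c(marginal = R2m, conditional = R2c),
       sigma2_typical = s2_typ)
}

#' Meta-regression with an additional moderator crossed with sex
#'
#' Same machinery as [fit_meta()] with design
#' `~ sex + moderator + sex:moderator`. Moderator levels with no data are
#' dropped with a warning (via the rank check on the design).
#'
#' @inheritParams fit_meta
#' @param moderator Name of a categorical column of `effects`.
#' @return A `meta_fit` object.
#' @export
fit_moderators <- function(effects, moderator, A_phylo = NULL,
                           config = meta_config(), force = FALSE) {
  if (!moderator %in% names(effects))
    stop("no column '", moderator, "' in effects", call. = FALSE)
  fit_meta(effects, A_phylo = A_phylo, config = config,
           moderator = moderator, force = force)
}

#' Egger-style publication-bias refit
#'
#' Refits the meta-regression with the sampling standard error `sqrt(V)` as
#' an additional continuous fixed covariate. A credible interval for the
#' slope that excludes zero flags funnel asymmetry (small, imprecise
#' effects systematically larger than precise ones).
#'
#' @inheritParams fit_meta
#' @return A `meta_fit` object; the slope is the `sei` parameter.
#' @export
publication_bias <- function(effects, A_phylo = NULL, config = meta_config(),
                             force = FALSE) {
  sei <- sqrt(effects$V)
  if (stats::sd(sei) == 0)
    stop("all sampling variances equal: Egger slope unestimable", call. = FALSE)
  fit_meta(effects, A_phylo = A_phylo, config = config,
           extra_fixed = list(sei = sei), force = force)
}
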