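#' Specification of a random-regression sire model fit
#'
#' Bundles the trait/covariate selection, Legendre order, chain settings,
#' residual-class count and variance priors for [gibbs_fit()].
#'
#' @param trait Trait column name.
#' @param covariate Environmental covariate column name.
#' @param order Legendre order of the sire regression (1 = intercept +
#'   slope, the default; 2 adds a quadratic coefficient).
#' @param n_iter,burn_in,thin Chain length, burn-in and thinning interval.
#'   The retained-draw count is `floor((n_iter - burn_in) / thin)`.
#' @param seed Integer seed; a fixed seed reproduces draws exactly.
#' @param residual_classes Number of covariate-quantile residual variance
#'   classes (default 10, i.e. decile classes).
#' @param priors Optional list overriding elements of the default weakly
#'   informative priors: `nu_g`, `V_g` (inverse-Wishart for the coefficient
#'   covariance), `nu_scalar`, `s2_scale_frac` (scaled inverse-chi-square
#'   for scalar variances, scale = `s2_scale_frac * var(y)`).
#' @return Object of class `rrm_spec`.
#' @export
rrm_spec <- function(trait, covariate, order = 1L, n_iter = 300000L,
                     burn_in = 50000L, thin = 50L, seed = 1L,
                     residual_classes = 10L, priors = list()) {
  stopifnot(order %in% c(1L, 2L), thin >= 1L, residual_classes >= 1L)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  q <- order + 1L
  defaults <- list(nu_g = 4, V_g = 0.1 * diag(q), nu_scalar = 3,
                   s2_scale_frac = 0.1)
  pr <- utils::modifyList(defaults, priors)
  structure(list(trait = trait, covariate = covariate, order = as.integer(order),
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 residual_classes = as.integer(residual_classes),
                 priors = pr),
            class = "rrm_spec")
}

#' Retained posterior draws implied by chain settings
#' @param spec An [rrm_spec()].
#' @return Integer, `floor((n_iter - burn_in) / thin)`.
#' @export
n_retained <- function(spec) {
  as.integer((spec$n_iter - spec$burn_in) %/% spec$thin)
}

#' Covariate-quantile residual variance classes
#'
#' Partitions records into `n_classes` classes of (approximately) equal size
#' by cutting the covariate at its `1/n, ..., (n-1)/n` quantiles -- decile
#' classes when `n_classes = 10`.  A record exactly on a cut point goes to
#' the lower class.
#'
#' @param covariate Numeric vector.
#' @param n_classes Number of classes (>= 1).
#' @return Integer vector of class indices in `1..n_classes`; attribute
#'   `cutpoints` holds the interior quantile cut points.
#' @export
assign_residual_classes <- function(covariate, n_classes = 10L) {
  if (n_classes < 1L) stop("n_classes must be >= 1")
  if (n_classes == 1L) {
    out <- rep(1L, length(covariate))
    attr(out, "cutpoints") <- numeric()
    return(out)
  }
  if (diff(base::range(covariate)) == 0) {
    stop("constant covariate cannot be split into ", n_classes, " classes")
  }
  probs <- seq_len(n_classes - 1L) / n_classes
  q <- stats::quantile(covariate, probs, names = FALSE)
  out <- findInterval(covariate, q, left.open = TRUE) + 1L
  attr(out, "cutpoints") <- q
  out
}

#' Assemble the model frame for the random-regression sire model
#'
#' Joins phenotypes to heat-load covariates, builds the fixed-effect design
#' (intercept, cross-fostering, parity, gender, dam line, and the Legendre
#' covariate regression), the per-record sire basis, batch/litter indices
#' and residual classes.  Records with missing values are dropped with a
#' logged count; aliased fixed-effect columns (e.g. a single-gender data
#' set) are dropped with a message.
#'
#' @param phen Phenotype data frame with columns `animal`, `sire`, `litter`,
#'   `batch`, `cf`, `parity`, `gender`, `dam_line` and the trait.
#' @param heatload Heat-load table from [lifetime_covariates()] (or any
#'   data frame with `animal` and the covariate column).
#' @param spec An [rrm_spec()].
#' @param standardization Optional `(min, max)` covariate range persisted
#'   from the screening stage; default is the range in the joined data.
#' @return Object of class `rrm_frame`.
#' @export
build_frame <- function(phen, heatload, spec, standardization = NULL) {
  dat <- if (spec$covariate %in% names(phen)) phen else
    merge(phen, heatload, by = "animal")
  need <- c("animal", "sire", "litter", "batch", "cf", "parity", "gender",
            "dam_line", spec$trait, spec$covariate)
  miss <- setdiff(need, names(dat))
  if (length(miss)) stop("model frame lacks column(s): ",
                         paste(miss, collapse = ", "))
  keep <- stats::complete.cases(dat[need])
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message("build_frame: dropped ", n_dropped,
            " record(s) with missing trait, covariate or factor values")
  }
  dat <- dat[keep, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no complete records to fit")

  cov <- dat[[spec$covariate]]
  rng <- if (is.null(standardization)) base::range(cov) else
    as.numeric(standardization)
  basis <- legendre_basis(cov, order = spec$order, range = rng)

  fac <- data.frame(cf = factor(dat$cf), parity = factor(dat$parity),
                    gender = factor(dat$gender),
                    dam_line = factor(dat$dam_line))
  one_level <- vapply(fac, function(f) nlevels(f) < 2L, TRUE)
  if (any(one_level)) {
    message("build_frame: factor(s) with a single level folded into the ",
            "intercept: ", paste(names(fac)[one_level], collapse = ", "))
    fac <- fac[!one_level]
  }
  X <- if (ncol(fac)) {
    stats::model.matrix(~ ., data = fac)
  } else {
    matrix(1, nrow(dat), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  X <- cbind(X, basis[, -1L, drop = FALSE])  # covariate regression (beta)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]
    message("build_frame: dropped aliased fixed-effect column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, -drop_cols, drop = FALSE]
  }

  sire_f <- factor(as.character(dat$sire))
  batch_f <- factor(as.character(dat$batch))
  litter_f <- factor(as.character(dat$litter))
  rclass <- assign_residual_classes(cov, spec$residual_classes)

  structure(list(
    y = as.numeric(dat[[spec$trait]]),
    X = X,
    B = unclass(basis)[, , drop = FALSE],   # per-record sire basis (1, s[, P2])
    covariate = cov,
    range = rng,
    sire = as.integer(sire_f), sire_ids = levels(sire_f),
    batch = as.integer(batch_f), batch_ids = levels(batch_f),
    litter = as.integer(litter_f), litter_ids = levels(litter_f),
    rclass = as.integer(rclass),
    cutpoints = attr(rclass, "cutpoints"),
    n_dropped = n_dropped,
    spec = spec
  ), class = "rrm_frame")
}

#' Gibbs sampler for the random-regression sire model
#'
#' Systematic-scan Gibbs sampler for
#' \deqn{y = X b + a_0(sire) + a_1(sire)\,\phi_1 [+ a_2(sire)\,\phi_2]
#'   + batch + litter + e}
#' with stacked sire coefficients `(a_0, a_1[, a_2])` distributed
#' `N(0, G2 (x) K)` (sires fastest within each coefficient), iid batch and
#' litter effects, and a separate residual variance per covariate-quantile
#' class.  Fixed effects get a flat prior; the coefficient covariance `G2`
#' an inverse-Wishart; scalar variances scaled inverse-chi-squares.
#'
#' @param frame An [build_frame()] result.
#' @param K Relationship kernel among the frame's sires (matrix with
#'   dimnames covering `frame$sire_ids`); typically [sire_block()] of an
#'   [h_matrix()].
#' @param spec The [rrm_spec()] used to build the frame.
#' @return Object of class `rrm_fit`: retained draws of all parameters plus
#'   metadata.  Draw matrices: `$fixed`, `$sire` (columns sire-major within
#'   coefficient), `$G` (unique coefficient-covariance entries), `$sigma2`
#'   (`batch`, `litter`, `e_1..e_T`).
#' @export
gibbs_fit <- function(frame, K, spec = frame$spec) {
  stopifnot(inherits(frame, "rrm_frame"))
  y <- frame$y; X <- frame$X; B <- frame$B
  n <- length(y); p <- ncol(X); q <- ncol(B)
  S <- length(frame$sire_ids)
  if (is.null(rownames(K)) || !all(frame$sire_ids %in% rownames(K))) {
    stop("K must carry dimnames covering all sires in the frame")
  }
  K <- K[frame$sire_ids, frame$sire_ids, drop = FALSE]
  Kinv <- tryCatch(chol2inv(chol(K)), error = function(e) {
    stop("sire kernel K is not positive definite: ", conditionMessage(e))
  })
  sire <- frame$sire; batch <- frame$batch; litter <- frame$litter
  rcl <- frame$rclass
  nb <- length(frame$batch_ids); nl <- length(frame$litter_ids)
  Tn <- spec$residual_classes

  # --- precomputations -----------------------------------------------------
  cls_f <- factor(rcl, levels = seq_len(Tn))
  # X'X per residual class
  XtX <- array(0, c(p, p, Tn))
  for (t in seq_len(Tn)) {
    it <- which(rcl == t)
    if (length(it)) XtX[, , t] <- crossprod(X[it, , drop = FALSE])
  }
  # per (sire, class) basis cross-products, and counts per (batch|litter, class)
  sc <- sire + S * (rcl - 1L)                     # sire-class cell
  pair_idx <- which(upper.tri(diag(q), diag = TRUE))
  BB <- matrix(0, n, length(pair_idx))
  k <- 0L
  pair_rc <- arrayInd(pair_idx, c(q, q))
  for (m in seq_len(nrow(pair_rc))) {
    BB[, m] <- B[, pair_rc[m, 1L]] * B[, pair_rc[m, 2L]]
  }
  Msc <- rowsum(BB, sc)                           # cells x pairs
  cell_of <- as.integer(rownames(Msc))
  M_pairs <- lapply(seq_len(ncol(Msc)), function(m) {
    M <- matrix(0, S, Tn)
    M[cbind((cell_of - 1L) %% S + 1L, (cell_of - 1L) %/% S + 1L)] <- Msc[, m]
    M
  })
  count_by <- function(idx, nlev) {
    M <- matrix(0, nlev, Tn)
    tab <- table(factor(idx, levels = seq_len(nlev)), cls_f)
    M[] <- as.numeric(tab)
    M
  }
  Nb <- count_by(batch, nb); Nl <- count_by(litter, nl)
  n_t <- as.numeric(table(cls_f))

  # --- priors and initial values ------------------------------------------
  pr <- spec$priors
  vy <- stats::var(y)
  s2_scale <- pr$s2_scale_frac * vy
  b <- qr.coef(qr(X), y)                          # OLS start
  b[is.na(b)] <- 0
  U <- matrix(0, S, q)                            # sire coefficients
  be <- numeric(nb); le <- numeric(nl)
  G2 <- diag(vy / 4, q)
  s2ba <- s2li <- vy / 4
  s2e <- rep(vy / 4, Tn)

  keep_n <- n_retained(spec)
  if (keep_n < 1L) stop("chain settings retain no draws")
  out_fixed <- matrix(NA_real_, keep_n, p, dimnames = list(NULL, colnames(X)))
  sire_cn <- paste0(rep(paste0("a", seq_len(q) - 1L), each = S), ".",
                    rep(frame$sire_ids, q))
  out_sire <- matrix(NA_real_, keep_n, S * q, dimnames = list(NULL, sire_cn))
  g_cn <- paste0("g", pair_rc[, 1L] - 1L, pair_rc[, 2L] - 1L)
  out_G <- matrix(NA_real_, keep_n, length(pair_idx),
                  dimnames = list(NULL, g_cn))
  out_s2 <- matrix(NA_real_, keep_n, 2L + Tn,
                   dimnames = list(NULL, c("batch", "litter",
                                           paste0("e_", seq_len(Tn)))))

  set.seed(spec$seed)
  fitted_parts <- function() {
    drop(X %*% b) + rowSums(B * U[sire, , drop = FALSE]) + be[batch] +
      le[litter]
  }
  e <- y - fitted_parts()
  kk <- 0L

  for (iter in seq_len(spec$n_iter)) {
    w_cls <- 1 / s2e
    w <- w_cls[rcl]

    ## (i) fixed effects (flat prior)
    e_x <- e + drop(X %*% b)
    Cx <- matrix(0, p, p)
    for (t in seq_len(Tn)) Cx <- Cx + w_cls[t] * XtX[, , t]
    rx <- crossprod(X, w * e_x)
    Rx <- tryCatch(chol(Cx), error = function(err) {
      stop("non-positive-definite fixed-effect conditional at iteration ",
           iter)
    })
    b <- drop(backsolve(Rx, backsolve(Rx, rx, transpose = TRUE) +
                              stats::rnorm(p)))
    e <- e_x - drop(X %*% b)

    ## (ii) stacked sire coefficients, prior precision G2^-1 (x) K^-1
    g_cur <- rowSums(B * U[sire, , drop = FALSE])
    e_u <- e + g_cur
    G2inv <- chol2inv(chol(G2))
    C <- matrix(0, S * q, S * q)
    for (m in seq_len(nrow(pair_rc))) {
      r <- pair_rc[m, 1L]; cc <- pair_rc[m, 2L]
      v <- drop(M_pairs[[m]] %*% w_cls)
      ir <- (r - 1L) * S + seq_len(S); ic <- (cc - 1L) * S + seq_len(S)
      C[cbind(ir, ic)] <- C[cbind(ir, ic)] + v
      if (r != cc) C[cbind(ic, ir)] <- C[cbind(ic, ir)] + v
    }
    for (r in seq_len(q)) for (cc in seq_len(q)) {
      ir <- (r - 1L) * S + seq_len(S); ic <- (cc - 1L) * S + seq_len(S)
      C[ir, ic] <- C[ir, ic] + G2inv[r, cc] * Kinv
    }
    we <- w * e_u
    ru <- unlist(lapply(seq_len(q), function(r)
      drop(rowsum(we * B[, r], sire))), use.names = FALSE)
    Ru <- tryCatch(chol(C), error = function(err) {
      stop("non-positive-definite sire-coefficient conditional at iteration ",
           iter)
    })
    u <- drop(backsolve(Ru, backsolve(Ru, ru, transpose = TRUE) +
                              stats::rnorm(S * q)))
    U <- matrix(u, S, q)
    e <- e_u - rowSums(B * U[sire, , drop = FALSE])

    ## (iii) batch and litter effects (iid priors)
    e_b <- e + be[batch]
    vb <- 1 / (drop(Nb %*% w_cls) + 1 / s2ba)
    mb <- vb * drop(rowsum(w * e_b, batch))
    be <- stats::rnorm(nb, mb, sqrt(vb))
    e <- e_b - be[batch]

    e_l <- e + le[litter]
    vl <- 1 / (drop(Nl %*% w_cls) + 1 / s2li)
    ml <- vl * drop(rowsum(w * e_l, litter))
    le <- stats::rnorm(nl, ml, sqrt(vl))
    e <- e_l - le[litter]

    ## (iv) coefficient covariance G2 ~ inverse-Wishart
    Su <- crossprod(U, Kinv %*% U)
    Vpost <- pr$V_g + Su
    G2inv_draw <- stats::rWishart(1L, pr$nu_g + S,
                                  chol2inv(chol(Vpost)))[, , 1L]
    G2 <- chol2inv(chol(G2inv_draw))
    G2 <- (G2 + t(G2)) / 2

    ## (v) scalar variances ~ scaled inverse-chi-square
    s2ba <- (pr$nu_scalar * s2_scale + sum(be^2)) /
      stats::rchisq(1L, pr$nu_scalar + nb)
    s2li <- (pr$nu_scalar * s2_scale + sum(le^2)) /
      stats::rchisq(1L, pr$nu_scalar + nl)
    SSe <- numeric(Tn)
    sse_g <- rowsum(e^2, rcl)
    SSe[as.integer(rownames(sse_g))] <- sse_g
    s2e <- (pr$nu_scalar * s2_scale + SSe) /
      stats::rchisq(Tn, pr$nu_scalar + n_t)

    if (iter %% 500L == 0L) {
      e <- y - fitted_parts()   # refresh against roundoff drift
      vmax <- max(diag(G2), s2ba, s2li, s2e)
      if (!is.finite(vmax) || vmax > 1e6 * vy) {
        stop("sampler divergence at iteration ", iter,
             ": a variance exceeded 1e6 x var(y)")
      }
    }

    if (iter > spec$burn_in && (iter - spec$burn_in) %% spec$thin == 0L) {
      kk <- kk + 1L
      if (kk <= keep_n) {
        out_fixed[kk, ] <- b
        out_sire[kk, ] <- u
        out_G[kk, ] <- G2[pair_idx]
        out_s2[kk, ] <- c(s2ba, s2li, s2e)
      }
    }
  }

  structure(list(
    fixed = out_fixed, sire = out_sire, G = out_G, sigma2 = out_s2,
    sire_ids = frame$sire_ids, order = spec$order, q = q,
    range = frame$range, cutpoints = frame$cutpoints,
    covariate = spec$covariate, trait = spec$trait, spec = spec,
    n_records = n
  ), class = "rrm_fit")
}

#' @export
print.rrm_fit <- function(x, ...) {
  cat("Random-regression sire model fit\n")
  cat("  trait:", x$trait, " covariate:", x$covariate,
      " order:", x$order, "\n")
  cat("  records:", x$n_records, " sires:", length(x$sire_ids), "\n")
  cat("  retained draws:", nrow(x$G), "\n")
  invisible(x)
}

# Effective sample size by Geyer's initial positive sequence
.ess <- function(x) {
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0) return(as.numeric(n))
  rho <- drop(stats::acf(x, lag.max = min(n - 2L, 1000L), plot = FALSE,
                         demean = TRUE)$acf)[-1L]
  tau <- 1
  m <- 1L
  while (m + 1L <= length(rho)) {
    pair <- rho[m] + rho[m + 1L]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    m <- m + 2L
  }
  min(n, n / tau)
}

#' Summarize posterior draws
#'
#' Per-parameter posterior mean, standard deviation, central 95% empirical
#' interval, and an effective-sample-size diagnostic.
#'
#' @param fit An [gibbs_fit()] result.
#' @param include_sires Include the per-sire coefficient draws (default
#'   `FALSE`; they can be numerous).
#' @return Data frame with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `q97.5`, `ess`.
#' @export
posterior_summary <- function(fit, include_sires = FALSE) {
  stopifnot(inherits(fit, "rrm_fit"))
  mats <- list(fit$fixed, fit$G, fit$sigma2)
  if (include_sires) mats <- c(mats, list(fit$sire))
  M <- do.call(cbind, mats)
  if (nrow(M) < 2L) stop("need at least 2 retained draws to summarize")
  qs <- apply(M, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(
    parameter = colnames(M),
    mean = colMeans(M),
    sd = apply(M, 2L, stats::sd),
    q2.5 = qs[1L, ], q97.5 = qs[2L, ],
    ess = apply(M, 2L, .ess),
    row.names = NULL
  )
}

#' Posterior-mean sire reaction-norm coefficients
#'
#' @param fit An [gibbs_fit()] result.
#' @return Data frame `sire`, `a0`, `a1` (and `a2` for order-2 fits) of
#'   posterior means.
#' @export
sire_solutions <- function(fit) {
  stopifnot(inherits(fit, "rrm_fit"))
  S <- length(fit$sire_ids)
  m <- colMeans(fit$sire)
  out <- data.frame(sire = fit$sire_ids)
  for (r in seq_len(fit$q)) {
    out[[paste0("a", r - 1L)]] <- m[(r - 1L) * S + seq_len(S)]
  }
  out
}
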