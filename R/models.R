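#' Inverse-variance random-effects meta-regression
#'
#' Fits the mixed-effects model `y_i = x_i' beta + u_i + e_i` with
#' `u_i ~ N(0, tau2)` and `e_i ~ N(0, v_i)` for known per-site sampling
#' variances `v_i` — each site's effect size (e.g. a richness-change
#' logratio) is weighted by the inverse of its total variance, so sites with
#' more reliable estimates carry more weight. `tau2` is estimated by REML
#' (default), ML, or DerSimonian–Laird moments; coefficients are
#' generalised-least-squares with Wald z tests. AICc is computed from the ML
#' likelihood so that models differing in moderators are comparable.
#'
#' @param yi numeric effect sizes, one per site.
#' @param vi nonnegative sampling variances (same length).
#' @param mods optional data frame / matrix of moderators (no intercept
#'   column; an intercept is added unless `intercept = FALSE`).
#' @param method `"REML"` (default), `"ML"`, or `"DL"`.
#' @param intercept include an intercept (default TRUE).
#' @return object of class `meta_fit`: coefficient table (`beta`, `se`,
#'   `zval`, `pval`), `tau2`, `k`, `p`, `aicc`, `loglik_ml`, `method`,
#'   plus the data (`yi`, `vi`, `X`) for downstream checks.
#' @export
meta_regress <- function(yi, vi, mods = NULL, method = c("REML", "ML", "DL"),
                         intercept = TRUE) {
  method <- match.arg(method)
  yi <- as.numeric(yi); vi <- as.numeric(vi)
  k <- length(yi)
  if (length(vi) != k) stop2("`yi` and `vi` lengths differ", class = "pollscape_domain_error")
  if (any(!is.finite(yi)) || any(!is.finite(vi)) || any(vi < 0)) {
    stop2("effects must be finite and variances nonnegative",
          class = "pollscape_domain_error")
  }
  X <- build_design(mods, k, intercept)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop2("singular design; collinear column(s): ", paste(bad, collapse = ", "),
          class = "pollscape_singular_error")
  }
  if (k < p + 2) {
    stop2(sprintf("too few sites (k = %d) for %d parameters", k, p),
          class = "pollscape_domain_error")
  }

  gls <- function(tau2) {
    w <- 1 / (vi + tau2)
    xtwx <- crossprod(X, w * X)
    beta <- solve(xtwx, crossprod(X, w * yi))
    r <- yi - X %*% beta
    list(w = w, xtwx = xtwx, beta = drop(beta), resid = drop(r),
         q = sum(w * r^2))
  }
  neg2_reml <- function(tau2) {
    f <- gls(tau2)
    sum(log(vi + tau2)) + determinant(f$xtwx)$modulus[1] + f$q
  }
  neg2_ml <- function(tau2) {
    f <- gls(tau2)
    sum(log(vi + tau2)) + f$q
  }

  upper <- max(stats::var(yi) * 10, max(vi), 1e-6)
  est_tau2 <- function(obj) {
    opt <- stats::optimize(obj, c(0, upper))
    # the boundary tau2 = 0 is admissible and optimize() never lands on it;
    # with v_i = 0 the boundary objective is undefined and stays interior
    val0 <- if (all(vi > 0)) obj(0) else Inf
    if (is.finite(val0) && val0 <= opt$objective) 0 else opt$minimum
  }
  tau2 <- switch(method,
    REML = est_tau2(neg2_reml),
    ML = est_tau2(neg2_ml),
    DL = {
      f0 <- gls(0)
      w <- 1 / vi
      P <- diag(w) - (w * X) %*% solve(crossprod(X, w * X), t(w * X))
      max(0, (f0$q - (k - p)) / sum(diag(P)))
    })
  fit <- gls(tau2)
  se <- sqrt(diag(solve(fit$xtwx)))
  zval <- fit$beta / se
  pval <- 2 * stats::pnorm(-abs(zval))

  tau2_ml <- if (method == "ML") tau2 else est_tau2(neg2_ml)
  ll_ml <- -0.5 * (neg2_ml(tau2_ml) + k * log(2 * pi))
  ptot <- p + 1  # coefficients + tau2
  aic <- -2 * ll_ml + 2 * ptot
  aicc <- if (k - ptot - 1 > 0) aic + 2 * ptot * (ptot + 1) / (k - ptot - 1) else Inf

  structure(list(
    beta = stats::setNames(fit$beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    zval = stats::setNames(zval, colnames(X)),
    pval = stats::setNames(pval, colnames(X)),
    tau2 = tau2, tau2_ml = tau2_ml, method = method,
    k = k, p = p, loglik_ml = ll_ml, aicc = aicc,
    fitted = drop(X %*% fit$beta), weights = fit$w,
    yi = yi, vi = vi, X = X
  ), class = "meta_fit")
}

build_design <- function(mods, k, intercept) {
  if (is.null(mods)) {
    X <- matrix(1, k, 1, dimnames = list(NULL, "intrcpt"))
    if (!intercept) stop2("a model needs an intercept or moderators",
                          class = "pollscape_domain_error")
    return(X)
  }
  M <- as.matrix(as.data.frame(mods))
  if (nrow(M) != k) stop2("moderators have wrong length", class = "pollscape_domain_error")
  if (is.null(colnames(M))) colnames(M) <- paste0("x", seq_len(ncol(M)))
  if (intercept) cbind(intrcpt = 1, M) else M
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf("<meta_fit> k = %d, tau2(%s) = %.5f, AICc = %.2f\n",
              x$k, x$method, x$tau2, x$aicc))
  print(round(cbind(estimate = x$beta, se = x$se, z = x$zval, p = x$pval), 4))
  invisible(x)
}

#' @export
coef.meta_fit <- function(object, ...) object$beta

#' Heterogeneity accounted for by a moderator model (VAF)
#'
#' The percentage of the between-site heterogeneity (`tau2`) present under
#' the intercept-only null model that is absorbed by the moderators:
#' `VAF = 100 * (tau2_null - tau2_model) / tau2_null`. A negative raw value
#' is reported as-is; when `tau2_null = 0` the statistic is undefined and
#' `NA` is returned with attribute `undefined = TRUE`.
#'
#' @param null_fit,model_fit `meta_fit` objects on identical data (same
#'   sites, same effect sizes).
#' @return numeric percentage (possibly negative), or `NA` if undefined.
#' @export
vaf <- function(null_fit, model_fit) {
  stopifnot(inherits(null_fit, "meta_fit"), inherits(model_fit, "meta_fit"))
  if (null_fit$k != model_fit$k || !isTRUE(all.equal(null_fit$yi, model_fit$yi))) {
    stop2("fits are not on the same sites/effects", class = "pollscape_domain_error")
  }
  if (null_fit$tau2 == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  structure(100 * (null_fit$tau2 - model_fit$tau2) / null_fit$tau2,
            undefined = FALSE)
}

# AICc for an lm/glm fit (df from logLik includes the error variance).
aicc_lm <- function(fit) {
  ll <- stats::logLik(fit)
  ptot <- attr(ll, "df")
  k <- stats::nobs(fit)
  if (k - ptot - 1 <= 0) return(Inf)
  -2 * as.numeric(ll) + 2 * ptot + 2 * ptot * (ptot + 1) / (k - ptot - 1)
}

#' Constrained backward stepwise model selection by AICc
#'
#' Backward elimination from the full admissible model until no single-term
#' deletion lowers AICc — the "minimum adequate model". Three constraint
#' families are honoured: (i) forbidden predictor pairs (from
#' [screen_collinearity()]) never co-occur; (ii) interactions (optional,
#' all two-way) are only retained alongside both main effects; (iii) the
#' caller supplies candidates from a single predictor family and spatial
#' scale per call (cover-change vs edge-change predictors, and different
#' buffer scales, belong in separate models). When forbidden pairs make the
#' full candidate set inadmissible, every maximal admissible subset (maximal
#' independent set of the conflict graph) is searched and the best final
#' AICc wins. Deterministic: ties break by preferring the smaller model,
#' then by lexicographic term name.
#'
#' @param data data frame holding the response, predictors, and (for the
#'   meta engine) a variance column.
#' @param response name of the response column.
#' @param candidates character vector of candidate predictor columns.
#' @param forbidden two-column character matrix of barred pairs (may be
#'   `NULL`).
#' @param engine `"meta"` (inverse-variance random-effects, requires
#'   `var_col`) or `"glm"` (Gaussian identity-link).
#' @param var_col name of the sampling-variance column (meta engine).
#' @param include_interactions add all two-way interactions of the
#'   admissible mains to the full model (dropped with a warning when the
#'   site count cannot support them).
#' @return list of class `stepwise_fit`: `terms` (retained), `fit` (final
#'   engine fit; meta fits are refit by REML), `aicc`, `start_terms`,
#'   `evaluated` (list of every term set scored), `engine`.
#' @export
stepwise_select <- function(data, response, candidates, forbidden = NULL,
                            engine = c("meta", "glm"), var_col = "var",
                            include_interactions = FALSE) {
  engine <- match.arg(engine)
  data <- as.data.frame(data)
  stopifnot(response %in% names(data), all(candidates %in% names(data)))
  if (engine == "meta" && !var_col %in% names(data)) {
    stop2("meta engine needs a variance column", class = "pollscape_config_error")
  }
  candidates <- sort(unique(candidates))
  k <- nrow(data)
  evaluated <- list()

  fit_terms <- function(terms, method = if (engine == "meta") "ML" else NULL) {
    evaluated[[length(evaluated) + 1L]] <<- sort(terms)
    X <- term_matrix(data, terms)
    if (engine == "meta") {
      f <- meta_regress(data[[response]], data[[var_col]], mods = X, method = method)
      list(fit = f, aicc = f$aicc)
    } else {
      df <- stats::setNames(data[response], ".y")
      rhs <- "1"
      if (!is.null(X)) {
        Xdf <- as.data.frame(X)
        names(Xdf) <- colnames(X)  # keep "a:b" labels unmangled
        df <- cbind(df, Xdf)
        rhs <- paste0("`", colnames(X), "`")
      }
      f <- stats::lm(stats::reformulate(rhs, ".y"), data = df)
      list(fit = f, aicc = aicc_lm(f))
    }
  }

  subsets <- admissible_subsets(candidates, forbidden)
  best <- NULL
  for (sub in subsets) {
    terms <- sub
    if (include_interactions && length(sub) >= 2L) {
      inter <- utils::combn(sub, 2L, function(z) paste(z, collapse = ":"))
      if (k >= length(sub) + length(inter) + 3L) terms <- c(sub, inter)
      else warn2("too few sites for two-way interactions; mains only",
                 class = "pollscape_interaction_skip")
    }
    while (k < length(terms) + 3L && length(terms)) terms <- terms[-length(terms)]
    res <- backward_eliminate(terms, fit_terms)
    if (is.null(best) || res$aicc < best$aicc - 1e-12 ||
        (abs(res$aicc - best$aicc) <= 1e-12 &&
         (length(res$terms) < length(best$terms) ||
          (length(res$terms) == length(best$terms) &&
           paste(res$terms, collapse = "+") < paste(best$terms, collapse = "+"))))) {
      best <- res
    }
  }
  final_fit <- if (engine == "meta") {
    X <- term_matrix(data, best$terms)
    meta_regress(data[[response]], data[[var_col]], mods = X, method = "REML")
  } else best$fit
  structure(list(terms = best$terms, fit = final_fit, aicc = best$aicc,
                 start_terms = best$start_terms, evaluated = evaluated,
                 engine = engine),
            class = "stepwise_fit")
}

# model matrix for main-effect and "a:b" interaction term labels
term_matrix <- function(data, terms) {
  if (!length(terms)) return(NULL)
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    Reduce(`*`, lapply(parts, function(p) data[[p]]))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  m
}

backward_eliminate <- function(terms, fit_terms) {
  start <- terms
  cur <- fit_terms(terms)
  repeat {
    if (!length(terms)) break
    in_inter <- unique(unlist(strsplit(grep(":", terms, value = TRUE), ":")))
    droppable <- sort(terms[grepl(":", terms) | !(terms %in% in_inter)])
    if (!length(droppable)) break
    trials <- lapply(droppable, function(d) fit_terms(setdiff(terms, d)))
    aiccs <- vapply(trials, `[[`, 1, "aicc")
    j <- which.min(aiccs)  # ties: first = lexicographic (droppable sorted)
    if (aiccs[j] <= cur$aicc + 1e-12) {
      terms <- setdiff(terms, droppable[j])
      cur <- trials[[j]]
    } else break
  }
  list(terms = sort(terms), fit = cur$fit, aicc = cur$aicc, start_terms = start)
}

# maximal admissible candidate subsets under forbidden-pair constraints
admissible_subsets <- function(candidates, forbidden) {
  if (is.null(forbidden) || nrow(forbidden) == 0L) return(list(candidates))
  fb <- forbidden[forbidden[, 1] %in% candidates & forbidden[, 2] %in% candidates, ,
                  drop = FALSE]
  if (nrow(fb) == 0L) return(list(candidates))
  g <- igraph::graph_from_data_frame(as.data.frame(fb), directed = FALSE,
                                     vertices = data.frame(name = candidates))
  ivs <- igraph::max_ivs(g)
  sets <- lapply(ivs, function(v) sort(igraph::as_ids(v)))
  sets[order(vapply(sets, paste, "", collapse = "+"))]
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("<stepwise_fit:%s> retained: %s (AICc %.2f)\n", x$engine,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "(intercept only)",
              x$aicc))
  invisible(x)
}

#' General linear model for species composition change
#'
#' SCC is a bounded index with no per-site standard error, so it is
#' modelled by an ordinary Gaussian identity-link linear model rather than
#' an inverse-variance weighted regression; simplification uses the same
#' constrained stepwise AICc engine.
#'
#' @inheritParams stepwise_select
#' @return a `stepwise_fit` (engine `"glm"`). A zero-variance response
#'   short-circuits to the intercept-only model with a warning.
#' @export
glm_composition <- function(data, response = "scc", candidates, forbidden = NULL,
                            include_interactions = FALSE) {
  data <- as.data.frame(data)
  if (stats::var(data[[response]]) == 0) {
    warn2("zero-variance response: intercept-only model",
          class = "pollscape_zero_variance")
    df <- stats::setNames(data[response], ".y")
    f <- stats::lm(.y ~ 1, data = df)
    return(structure(list(terms = character(), fit = f, aicc = aicc_lm(f),
                          start_terms = character(), evaluated = list(character()),
                          engine = "glm"),
                     class = "stepwise_fit"))
  }
  stepwise_select(data, response, candidates, forbidden, engine = "glm",
                  include_interactions = include_interactions)
}

#' Check and correct residual sampling-effort bias
#'
#' Even effort-corrected richness change can retain a signature of the raw
#' effort imbalance `delta_r = ln(n2 / n1)`. The logratios are regressed on
#' `delta_r` (inverse-variance weighted); if the slope is significant the
#' effects are replaced by partial residuals (the fitted `delta_r`
#' component removed, intercept retained), otherwise passed through
#' unchanged. Sampling variances are kept as supplied either way.
#'
#' @param logratios per-site effect sizes.
#' @param variances per-site sampling variances.
#' @param delta_r per-site `ln(n2/n1)`.
#' @param alpha significance threshold (default 0.05).
#' @return list with `effects`, `adjusted` (logical), `skipped` (logical),
#'   `p` (slope p-value, `NA` when skipped), `fit`.
#' @export
sampling_bias_check <- function(logratios, variances, delta_r, alpha = 0.05) {
  if (any(!is.finite(delta_r))) {
    stop2("delta_r must be finite for every site", class = "pollscape_domain_error")
  }
  if (stats::var(delta_r) == 0) {
    warn2("constant delta_r: sampling-bias check skipped",
          class = "pollscape_constant_deltar")
    return(list(effects = logratios, adjusted = FALSE, skipped = TRUE,
                p = NA_real_, fit = NULL))
  }
  fit <- meta_regress(logratios, variances, mods = data.frame(delta_r = delta_r))
  p <- unname(fit$pval["delta_r"])
  if (p < alpha) {
    eff <- logratios - fit$beta["delta_r"] * delta_r
    list(effects = unname(eff), adjusted = TRUE, skipped = FALSE, p = p, fit = fit)
  } else {
    list(effects = logratios, adjusted = FALSE, skipped = FALSE, p = p, fit = fit)
  }
}

#' Moran's I spatial autocorrelation screen
#'
#' Tests site-level values (land-cover change, richness change, SCC) for
#' spatial autocorrelation before regression, using inverse-distance
#' weights (zero diagonal, row-normalised) and the normal approximation.
#' Expected value under no autocorrelation is `-1/(k-1)`.
#'
#' @param values numeric vector, one per site.
#' @param coords two-column matrix of site coordinates.
#' @return list with `observed`, `expected`, `sd`, `p`, `undefined`.
#' @export
morans_i <- function(values, coords) {
  coords <- as.matrix(coords)
  k <- length(values)
  if (k < 4L || nrow(coords) != k) {
    stop2("need >= 4 sites with matching coordinates", class = "pollscape_domain_error")
  }
  if (stats::var(values) == 0) {
    return(list(observed = NA_real_, expected = -1 / (k - 1), sd = NA_real_,
                p = NA_real_, undefined = TRUE))
  }
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] == 0)) {
    warn2("duplicate coordinates offset by epsilon", class = "pollscape_dup_coords")
    eps <- max(d) * 1e-6 + 1e-12
    d[d == 0] <- eps
  }
  w <- 1 / d
  diag(w) <- 0
  w <- w / rowSums(w)
  res <- ape::Moran.I(values, w, scaled = FALSE, alternative = "two.sided")
  list(observed = res$observed, expected = res$expected, sd = res$sd,
       p = res$p.value, undefined = FALSE)
}
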