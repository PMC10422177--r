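# Reference implementation used for validation: explicit dummy-variable OLS
# via stats::lm plus a hand-assembled cluster sandwich. Deliberately shares no
# code with the alternating-projection engine, so the two can check each
# other on small panels.

#' Dummy-variable OLS with a cluster sandwich (validation oracle)
#'
#' Fits the same model as [fe_fit()] by expanding every fixed-effect dimension
#' into explicit factor dummies and calling [stats::lm()], then computes the
#' CR1 cluster-robust covariance directly from the full dummy design. Only
#' feasible on small panels; intended for validating the demeaning engine.
#'
#' @inheritParams fe_fit
#' @return List with `coef` and `se` for the spec's regressors, plus the lm
#'   `rank` of the full dummy design.
#' @export
fit_dummy_ols <- function(spec, panel) {
  stopifnot(inherits(spec, "model_spec"))
  pan <- data.table::as.data.table(panel)
  df <- data.frame(.y = as.numeric(pan[[spec$outcome]]))
  for (r in spec$regressors) df[[r]] <- as.numeric(pan[[r]])
  fnames <- character()
  for (j in seq_along(spec$fe)) {
    fn <- paste0(".fe", j)
    df[[fn]] <- factor(fe_codes(pan, spec$fe[j]))
    fnames <- c(fnames, fn)
  }
  fml <- stats::as.formula(paste(
    ".y ~", paste(c(sprintf("`%s`", spec$regressors), fnames), collapse = " + ")
  ))
  fit <- stats::lm(fml, data = df, singular.ok = TRUE)
  cf <- stats::coef(fit)
  keep <- names(cf)[!is.na(cf)]
  X <- stats::model.matrix(fit)[, keep, drop = FALSE]
  e <- stats::residuals(fit)
  n <- nrow(X)
  K <- fit$rank
  cl <- fe_codes(pan, spec$cluster)
  G <- max(cl)

  # same CR1 dof convention as the engine, derived independently from the lm
  # rank and a direct nestedness check of each factor against the clusters
  K_crv <- K
  if ((spec$dof %||% "nested") == "nested") {
    for (fn in fnames) {
      f <- df[[fn]]
      if (nrow(unique(cbind(as.integer(f), cl))) == nlevels(f)) {
        K_crv <- K_crv - nlevels(f)
      }
    }
    K_crv <- max(length(spec$regressors), K_crv)
  }
  bread <- solve(crossprod(X))
  S <- rowsum(X * e, cl, reorder = FALSE)
  meat <- crossprod(S)
  adj <- (G / (G - 1)) * ((n - 1) / (n - K_crv))
  V <- adj * bread %*% meat %*% bread

  want <- sprintf("`%s`", spec$regressors)
  alt <- spec$regressors
  idx <- ifelse(want %in% colnames(X), want, alt)
  list(coef = stats::setNames(cf[idx], spec$regressors),
       se = stats::setNames(sqrt(diag(V)[idx]), spec$regressors),
       rank = K)
}
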