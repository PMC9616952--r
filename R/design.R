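# Design-matrix construction for the binomial-Normal meta-regression:
# treatment-coded categorical fixed effects and the mixed-model
# (Demmler-Reinsch) representation of penalized B-spline smooths.

build_fixed_design <- function(df, fixed, interactions) {
  if (!length(fixed)) {
    return(list(X = matrix(0, nrow(df), 0), terms = NULL, xlevels = list()))
  }
  for (f in fixed) {
    if (!f %in% names(df)) abort(paste0("moderator not in data: ", f))
    df[[f]] <- factor(df[[f]], levels = sort(unique(as.character(df[[f]]))))
  }
  rhs <- c(fixed, interactions)
  form <- stats::reformulate(rhs)
  mf <- stats::model.frame(form, df)
  tt <- attr(mf, "terms")
  X <- model.matrix(tt, mf)
  xlev <- stats::.getXlevels(tt, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  const <- apply(X, 2, function(col) length(unique(col)) == 1L)
  X <- X[, !const, drop = FALSE]
  list(X = X, terms = tt, xlevels = xlev)
}

# penalized cubic B-spline with second-difference penalty, reparametrized
# into an unpenalised linear column plus iid-Normal spline coefficients
build_spline_design <- function(z, k, var_name) {
  if (anyNA(z)) {
    abort(paste0("missing values in spline covariate '", var_name,
                 "'; impute first (see impute_missing)"))
  }
  n_unique <- length(unique(z))
  if (n_unique < 5L) {
    warn(paste0("covariate '", var_name, "' has ", n_unique,
                " unique values; using a linear term only"))
    ctr <- mean(z); scl <- max(sd(z), 1e-8)
    return(list(var = var_name, linear = (z - ctr) / scl, Z = NULL,
                center = ctr, scale = scl, basis = NULL, transform = NULL))
  }
  k <- min(k, n_unique - 1L)
  ctr <- mean(z); scl <- max(sd(z), 1e-8)
  zs <- (z - ctr) / scl
  basis <- splines::bs(zs, df = k, degree = 3, intercept = TRUE)
  D <- diff(diag(k), differences = 2)
  S <- crossprod(D)
  eg <- eigen(S, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  transform <- eg$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[pos]), sum(pos))
  Z <- basis %*% transform
  list(var = var_name, linear = zs, Z = Z, center = ctr, scale = scl,
       basis = basis, transform = transform,
       range = range(zs))
}

spline_design_at <- function(sp, z_new) {
  zs <- (z_new - sp$center) / sp$scale
  if (is.null(sp$Z)) return(list(linear = zs, Z = NULL))
  zs_cl <- pmin(pmax(zs, sp$range[1]), sp$range[2])  # clamp outside range
  B <- predict(sp$basis, zs_cl)
  list(linear = zs, Z = B %*% sp$transform)
}

# population-level linear predictor (group effects at zero) for new data:
# draws x rows matrix
predict_eta_pop <- function(fit, newdata) {
  nd <- tibble::as_tibble(newdata)
  total <- dim(fit$draws)[1] * dim(fit$draws)[2]
  eta <- matrix(rep(flat_draws(fit, "b0"), nrow(nd)), total, nrow(nd))
  des <- fit$design
  if (!is.null(des$terms)) {
    for (f in names(des$xlevels)) {
      vals <- as.character(nd[[f]])
      bad <- !vals %in% des$xlevels[[f]]
      if (any(bad)) abort(paste0("level(s) of ", f, " not seen at fit time: ",
                                 paste(unique(vals[bad]), collapse = ", ")))
      nd[[f]] <- factor(vals, levels = des$xlevels[[f]])
    }
    tt <- stats::delete.response(des$terms)
    X <- model.matrix(tt, stats::model.frame(tt, nd, xlev = des$xlevels))
    X <- X[, colnames(des$X), drop = FALSE]
    if (ncol(X)) {
      B <- flat_draws(fit, colnames(des$X))
      eta <- eta + B %*% t(X)
    }
  }
  for (sp in des$splines) {
    at <- spline_design_at(sp, nd[[sp$var]])
    bl <- flat_draws(fit, paste0("lin_", sp$var))
    eta <- eta + cbind(bl) %*% rbind(at$linear)
    if (!is.null(at$Z)) {
      bs_names <- paste0("spl_", sp$var, "[", seq_len(ncol(sp$Z)), "]")
      Bsp <- flat_draws(fit, bs_names)
      eta <- eta + Bsp %*% t(at$Z)
    }
  }
  eta
}

# draws for named parameters flattened over chains: total_draws x length(pars)
flat_draws <- function(fit, pars) {
  d <- fit$draws
  out <- vapply(pars, function(p) {
    if (!p %in% dimnames(d)[[3]]) abort(paste0("no such parameter: ", p))
    as.numeric(d[, , p])
  }, numeric(dim(d)[1] * dim(d)[2]))
  if (length(pars) == 1L) matrix(out, ncol = 1, dimnames = list(NULL, pars))
  else out
}
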