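#' Sex-limitation model specifications (Models I-VI)
#'
#' The nested model ladder of the five-group sex-limitation ACE design:
#' \describe{
#'   \item{I}{general model — all seven variance paths free
#'     (`a_f, c_f, e_f, a_m, c_m, e_m, am_prime`).}
#'   \item{II}{common-effects model — drop the male-specific additive
#'     path (`am_prime = 0`); 6 paths.}
#'   \item{III}{additionally `c_m = 0`; 5 paths.}
#'   \item{IV}{additionally `c_f = 0`; 4 paths.}
#'   \item{V}{AE model with paths equal across sexes; 2 paths.}
#'   \item{VI}{ACE model with paths equal across sexes; 3 paths.}
#' }
#' Models V and VI implement sex-limitation by strict cross-sex equality
#' of paths, which is what reproduces the published degrees of freedom; a
#' scalar-multiplier variant (`scalar = TRUE`, one extra parameter
#' scaling all female paths relative to the male ones) is available but
#' does not match those df.
#'
#' @param id One of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`, `"VI"`.
#' @param scalar Use the scalar-multiplier variant of Models V/VI.
#' @return An object of class `ace_model_spec`.
#' @export
model_spec <- function(id = c("I", "II", "III", "IV", "V", "VI"),
                       scalar = FALSE) {
  id <- match.arg(id)
  paths <- switch(id,
    I = c("a_f", "c_f", "e_f", "a_m", "c_m", "e_m", "am_prime"),
    II = c("a_f", "c_f", "e_f", "a_m", "c_m", "e_m"),
    III = c("a_f", "c_f", "e_f", "a_m", "e_m"),
    IV = c("a_f", "e_f", "a_m", "e_m"),
    V = c("a", "e"),
    VI = c("a", "c", "e"))
  equal <- id %in% c("V", "VI")
  if (scalar && !equal)
    stop("the scalar variant applies to Models V and VI only")
  if (scalar) paths <- c(paths, "k_f")
  structure(list(id = id, paths = paths, equal_sexes = equal,
                 scalar = scalar, n_paths = length(paths)),
            class = "ace_model_spec")
}

# expand a free-path vector into full sexlim parameters (list, not class,
# so intermediate optimizer states with e = 0 are representable)
.theta_to_params <- function(theta, spec) {
  p <- list(a_f = 0, c_f = 0, e_f = 0, a_m = 0, c_m = 0, e_m = 0,
            am_prime = 0)
  th <- stats::setNames(theta, spec$paths)
  if (spec$equal_sexes) {
    k <- if (spec$scalar) th[["k_f"]] else 1
    for (nm in intersect(c("a", "c", "e"), spec$paths)) {
      p[[paste0(nm, "_m")]] <- th[[nm]]
      p[[paste0(nm, "_f")]] <- k * th[[nm]]
    }
  } else {
    for (nm in spec$paths) p[[nm]] <- th[[nm]]
  }
  p
}

# model-implied 2x2 covariance for one zygosity-sex group
.group_cov <- function(p, group) {
  var_f <- p$a_f^2 + p$c_f^2 + p$e_f^2
  var_m <- p$a_m^2 + p$am_prime^2 + p$c_m^2 + p$e_m^2
  switch(group,
    MZf = matrix(c(var_f, p$a_f^2 + p$c_f^2,
                   p$a_f^2 + p$c_f^2, var_f), 2),
    MZm = matrix(c(var_m, p$a_m^2 + p$am_prime^2 + p$c_m^2,
                   p$a_m^2 + p$am_prime^2 + p$c_m^2, var_m), 2),
    DZf = matrix(c(var_f, 0.5 * p$a_f^2 + p$c_f^2,
                   0.5 * p$a_f^2 + p$c_f^2, var_f), 2),
    DZm = matrix(c(var_m,
                   0.5 * p$a_m^2 + 0.5 * p$am_prime^2 + p$c_m^2,
                   0.5 * p$a_m^2 + 0.5 * p$am_prime^2 + p$c_m^2, var_m), 2),
    DZos = matrix(c(var_f, 0.5 * p$a_f * p$a_m + p$c_f * p$c_m,
                    0.5 * p$a_f * p$a_m + p$c_f * p$c_m, var_m), 2),
    stop("unknown group label: ", group))
}

#' Model-implied moments for one twin pair
#'
#' Expected mean vector and 2x2 covariance matrix for a pair in a given
#' zygosity-sex group under sex-limitation ACE parameters. Twin order is
#' (twin 1, twin 2); opposite-sex pairs are (female, male).
#'
#' @param params A [sexlim_parameters()] object (or plain list of paths).
#' @param group Group label: MZm, MZf, DZm, DZf or DZos.
#' @param beta Optional means-model coefficient vector.
#' @param x1,x2 Optional design rows (one per twin) multiplying `beta`;
#'   when omitted the mean is `c(0, 0)`.
#' @return List with `mean` (length 2) and `cov` (2x2).
#' @export
expected_moments <- function(params, group, beta = NULL, x1 = NULL,
                             x2 = NULL) {
  mu <- if (is.null(beta)) c(0, 0)
        else c(sum(x1 * beta), sum(x2 * beta))
  list(mean = mu, cov = .group_cov(as.list(params), group))
}

#' Default means-model design (5 free coefficients)
#'
#' Per-twin design columns: female intercept, male intercept, centered
#' age (years - 50), centered BMI (kg/m^2 - 24.5), and an age-by-male
#' interaction. Five coefficients reproduce the published model degrees
#' of freedom at 379 pairs; df is always recomputed from the design
#' actually used.
#'
#' @param twins Data frame of twins (rows) with `sex`, `age`, `bmi`.
#' @return Numeric design matrix, one row per twin.
#' @export
means_design_default <- function(twins) {
  male <- as.numeric(twins$sex == "M")
  cbind(int_f = 1 - male, int_m = male,
        age_c = twins$age - 50, bmi_c = twins$bmi - 24.5,
        age_x_male = (twins$age - 50) * male)
}

#' Intercept-only means design (2 coefficients)
#'
#' Sex-specific intercepts and no covariates; useful for cohorts
#' simulated without covariate effects.
#' @param twins Data frame of twins with a `sex` column.
#' @return Two-column design matrix.
#' @export
means_design_intercepts <- function(twins) {
  male <- as.numeric(twins$sex == "M")
  cbind(int_f = 1 - male, int_m = male)
}

# Sufficient statistics per group for the FIML likelihood: with constant
# within-group covariance and means linear in covariates, -2LL depends on
# the data only through cross-products, so likelihood evaluations and the
# GLS profile of the mean coefficients are O(p^2), independent of n.
.fiml_prep <- function(cohort, means_design, value_col = "sua") {
  pr <- cohort_pairs(cohort)
  X1 <- means_design(pr$t1); X2 <- means_design(pr$t2)
  y1 <- pr$t1[[value_col]]; y2 <- pr$t2[[value_col]]
  if (anyNA(y1) || anyNA(y2)) stop("FIML requires complete pairs")
  groups <- list()
  for (g in unique(pr$group)) {
    i <- pr$group == g
    A1 <- X1[i, , drop = FALSE]; A2 <- X2[i, , drop = FALSE]
    b1 <- y1[i]; b2 <- y2[i]
    groups[[g]] <- list(
      n = sum(i),
      S11 = crossprod(A1), S22 = crossprod(A2), S12 = crossprod(A1, A2),
      u1 = drop(crossprod(A1, b1)), u2 = drop(crossprod(A2, b2)),
      v12 = drop(crossprod(A1, b2)), v21 = drop(crossprod(A2, b1)),
      q11 = sum(b1^2), q22 = sum(b2^2), q12 = sum(b1 * b2))
  }
  list(groups = groups, p = ncol(X1), coef_names = colnames(X1),
       n_pairs = length(y1))
}

.BARRIER <- 1e10

# -2LL from sufficient statistics at given paths and mean coefficients;
# beta = NULL profiles the mean coefficients by GLS and returns them in
# attr(, "beta")
.fiml_neg2ll <- function(pars, prep, beta = NULL) {
  invs <- list()
  for (g in names(prep$groups)) {
    S <- .group_cov(pars, g)
    det <- S[1, 1] * S[2, 2] - S[1, 2]^2
    if (!is.finite(det) || det <= 1e-12 || S[1, 1] <= 0) return(.BARRIER)
    invs[[g]] <- c(i11 = S[2, 2] / det, i12 = -S[1, 2] / det,
                   i22 = S[1, 1] / det, logdet = log(det))
  }
  if (is.null(beta)) {
    p <- prep$p
    M <- matrix(0, p, p); b <- numeric(p)
    for (g in names(prep$groups)) {
      d <- prep$groups[[g]]; iv <- invs[[g]]
      M <- M + iv["i11"] * d$S11 + iv["i22"] * d$S22 +
        iv["i12"] * (d$S12 + t(d$S12))
      b <- b + iv["i11"] * d$u1 + iv["i22"] * d$u2 +
        iv["i12"] * (d$v12 + d$v21)
    }
    beta <- tryCatch(solve(M, b), error = function(e) NULL)
    if (is.null(beta)) return(.BARRIER)
  }
  val <- 0
  for (g in names(prep$groups)) {
    d <- prep$groups[[g]]; iv <- invs[[g]]
    r11 <- d$q11 - 2 * sum(beta * d$u1) + drop(beta %*% d$S11 %*% beta)
    r22 <- d$q22 - 2 * sum(beta * d$u2) + drop(beta %*% d$S22 %*% beta)
    r12 <- d$q12 - sum(beta * d$v12) - sum(beta * d$v21) +
      drop(beta %*% d$S12 %*% beta)
    val <- val + d$n * (2 * log(2 * pi) + iv["logdet"]) +
      iv["i11"] * r11 + iv["i22"] * r22 + 2 * iv["i12"] * r12
  }
  structure(as.numeric(val), beta = beta)
}

#' FIML -2 log-likelihood of a twin cohort
#'
#' Sum over pairs of minus twice the log bivariate-normal density, with
#' group-specific model-implied covariance and per-twin means from the
#' covariate design (definition-variable style).
#'
#' @param params Sex-limitation parameters (full set; constrained paths
#'   at 0).
#' @param cohort Twin cohort data frame with complete pairs.
#' @param beta Means-model coefficients; `NULL` (default) treats the
#'   phenotype as already centered (zero mean).
#' @param means_design Design builder, see [means_design_default()].
#' @param value_col Phenotype column, default `"sua"`.
#' @return The -2 log-likelihood (scalar).
#' @export
neg2_loglik <- function(params, cohort, beta = NULL,
                        means_design = means_design_default,
                        value_col = "sua") {
  prep <- .fiml_prep(cohort, means_design, value_col)
  if (is.null(beta)) beta <- numeric(prep$p)  # zero mean, not profiled
  v <- .fiml_neg2ll(as.list(params), prep, beta = beta)
  if (v >= .BARRIER) stop("covariance matrix not positive definite")
  as.numeric(v)
}

# Falconer-style start: a^2 ~ 2(rMZ - rDZ), c^2 ~ 2 rDZ - rMZ, per sex,
# scaled by the observed per-sex variance; NULL when groups are missing
.falconer_start <- function(cohort, spec, value_col) {
  pr <- cohort_pairs(cohort)
  Y <- cbind(pr$t1[[value_col]], pr$t2[[value_col]])
  rg <- function(g) {
    i <- pr$group %in% g
    if (sum(i) < 4) return(NA_real_)
    stats::cor(Y[i, 1], Y[i, 2])
  }
  shares <- function(rmz, rdz) {
    if (is.na(rmz) || is.na(rdz)) return(NULL)
    a2 <- min(max(2 * (rmz - rdz), 0.02), 0.9)
    c2 <- min(max(2 * rdz - rmz, 0.02), 0.9)
    e2 <- max(1 - a2 - c2, 0.05)
    c(a2, c2, e2) / (a2 + c2 + e2)
  }
  vf <- stats::var(cohort[[value_col]][cohort$sex == "F"])
  vm <- stats::var(cohort[[value_col]][cohort$sex == "M"])
  sf <- shares(rg("MZf"), rg(c("DZf", "DZos")))
  sm <- shares(rg("MZm"), rg(c("DZm", "DZos")))
  if (spec$equal_sexes) {
    sp <- shares(rg(c("MZf", "MZm")), rg(c("DZf", "DZm", "DZos")))
    if (is.null(sp)) return(NULL)
    v <- mean(c(vf, vm), na.rm = TRUE)
    th <- sqrt(sp * v)
    names(th) <- c("a", "c", "e")
    out <- th[intersect(c("a", "c", "e"), spec$paths)]
    if (spec$scalar) out <- c(out, k_f = 1)
    return(out)
  }
  if (is.null(sf) || is.null(sm) || !is.finite(vf) || !is.finite(vm))
    return(NULL)
  full <- c(a_f = sqrt(sf[1] * vf), c_f = sqrt(sf[2] * vf),
            e_f = sqrt(sf[3] * vf), a_m = sqrt(sm[1] * vm),
            c_m = sqrt(sm[2] * vm), e_m = sqrt(sm[3] * vm),
            am_prime = 0.05 * sqrt(vm))
  full[spec$paths]
}

# numeric central-difference gradient norm of the profiled objective
.grad_norm <- function(obj, theta, h = 1e-5) {
  g <- vapply(seq_along(theta), function(j) {
    tp <- tm <- theta; tp[j] <- tp[j] + h; tm[j] <- max(tm[j] - h, 0)
    (obj(tp) - obj(tm)) / (tp[j] - tm[j])
  }, numeric(1))
  sqrt(sum(g^2))
}

#' Fit a sex-limitation ACE model by FIML
#'
#' Minimizes the -2 log-likelihood over the model's free variance paths
#' (bounded at 0, unique-environment paths kept positive), profiling the
#' means-model coefficients by generalized least squares at every
#' evaluation. Multiple restarts from Latin-hypercube draws over the
#' variance-share simplex guard against local minima.
#'
#' @param spec A [model_spec()] or model id string.
#' @param cohort Twin cohort data frame (complete pairs).
#' @param means_design Means design builder; its column count sets the
#'   number of mean parameters entering the df bookkeeping.
#' @param n_restarts Number of optimizer starts (default 10).
#' @param seed Seed for the restart draws.
#' @param tol Relative convergence tolerance on -2LL (default 1e-8).
#' @param value_col Phenotype column, default `"sua"`.
#' @return An object of class `ace_fit`: model id, estimated parameters,
#'   mean coefficients, `neg2ll`, `n_free_params`,
#'   `df = 2*n_pairs - n_free_params`, `aic` (Mx convention
#'   -2LL - 2 df), standardized `shares` (percent, per sex), and
#'   convergence diagnostics.
#' @export
fit_model <- function(spec, cohort, means_design = means_design_default,
                      n_restarts = 10, seed = 1L, tol = 1e-8,
                      value_col = "sua") {
  if (is.character(spec)) spec <- model_spec(spec)
  if (any(table(as.character(cohort$group)) < 4))
    stop("need at least 2 pairs in every group present")
  prep <- .fiml_prep(cohort, means_design, value_col)

  obj <- function(theta)
    as.numeric(.fiml_neg2ll(.theta_to_params(theta, spec), prep))

  k <- spec$n_paths
  # anchor starts: equal split of the observed phenotypic SD, plus a
  # Falconer-style start from the observed MZ/DZ correlations
  sd0 <- sqrt(max(stats::var(cohort[[value_col]]), 1e-8))
  starts <- matrix(rep(sd0 / sqrt(3), k), nrow = 1)
  falc <- .falconer_start(cohort, spec, value_col)
  if (!is.null(falc)) starts <- rbind(starts, falc)
  if (n_restarts > 1) {
    set.seed(seed)
    H <- lhs::randomLHS(n_restarts - 1, k)
    starts <- rbind(starts, sd0 * sqrt(H / rowSums(H) + 1e-3) *
                      matrix(stats::runif((n_restarts - 1), 0.7, 1.3),
                             n_restarts - 1, k))
  }
  if (spec$scalar) starts[, k] <- stats::runif(nrow(starts), 0.7, 1.3)
  lower <- rep(0, k)
  lower[grep("^e", spec$paths)] <- 1e-6
  names(lower) <- spec$paths

  best <- NULL; n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::nlminb(pmax(starts[i, ], lower + 1e-4), obj, lower = lower,
                    control = list(rel.tol = tol, iter.max = 500)),
      error = function(e) NULL)
    if (is.null(fit) || fit$objective >= .BARRIER) next
    if (fit$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best))
    stop("no restart converged to a finite likelihood")
  # high-precision polish of the best restart
  polish <- tryCatch(
    stats::nlminb(best$par, obj, lower = lower,
                  control = list(rel.tol = 1e-14, abs.tol = 1e-12,
                                 iter.max = 1000)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$objective <= best$objective)
    best <- polish

  theta <- stats::setNames(best$par, spec$paths)
  pars <- .theta_to_params(theta, spec)
  val <- .fiml_neg2ll(pars, prep)
  beta <- stats::setNames(attr(val, "beta"), prep$coef_names)
  n_free <- k + prep$p
  df <- 2L * prep$n_pairs - n_free
  fit <- structure(list(
    model = spec$id, spec = spec, params = pars, theta = theta,
    beta = beta, neg2ll = as.numeric(val), n_pairs = prep$n_pairs,
    n_free_params = n_free, df = df, aic = as.numeric(val) - 2 * df,
    shares = standardize_components(pars),
    convergence = list(code = best$convergence, restarts = nrow(starts),
                       n_converged = n_conv,
                       grad_norm = .grad_norm(obj, best$par)),
    prep = prep), class = "ace_fit")
  fit
}

#' @export
print.ace_fit <- function(x, digits = 2, ...) {
  cat(sprintf("Sex-limitation ACE fit, Model %s (%d pairs)\n",
              x$model, x$n_pairs))
  print(round(x$shares, digits))
  cat(sprintf("-2LL = %.2f  df = %d  AIC = %.2f  (free params: %d)\n",
              x$neg2ll, x$df, x$aic, x$n_free_params))
  invisible(x)
}

#' Standardized variance components per sex
#'
#' Percent of phenotypic variance attributed to A, C and E within each
#' sex. By default the male-specific additive contribution `am_prime^2`
#' is folded into the male additive share; `fold_am_prime = FALSE`
#' reports it as a fourth column (zero for females).
#'
#' @param params Sex-limitation parameters or an `ace_fit`.
#' @param fold_am_prime Fold `am_prime^2` into the male A share.
#' @return Matrix (rows female/male) of percentages summing to 100.
#' @export
standardize_components <- function(params, fold_am_prime = TRUE) {
  if (inherits(params, "ace_fit")) params <- params$params
  p <- as.list(params)
  vf <- c(A = p$a_f^2, C = p$c_f^2, E = p$e_f^2, Am = 0)
  vm <- c(A = p$a_m^2, C = p$c_m^2, E = p$e_m^2, Am = p$am_prime^2)
  if (sum(vf) <= 0 || sum(vm) <= 0) stop("zero total variance")
  if (fold_am_prime) {
    vf["A"] <- vf["A"] + vf["Am"]; vm["A"] <- vm["A"] + vm["Am"]
    vf <- vf[1:3]; vm <- vm[1:3]
  }
  out <- rbind(female = 100 * vf / sum(vf), male = 100 * vm / sum(vm))
  out
}

# ---- profile-likelihood confidence intervals --------------------------

# constrained -2LL minimized over nuisance parameters, with the target
# sex block reparameterized as (total sd, remaining-share splits) so the
# target standardized share is held at s
.profile_objective <- function(fit, component, s) {
  spec <- fit$spec; prep <- fit$prep
  if (spec$scalar)
    stop("profile CIs are not provided for the scalar variant")
  comp <- toupper(substr(component, 1, 1))   # A, C or E
  sex <- if (spec$equal_sexes) "both"
         else if (grepl("_f$", component, ignore.case = TRUE)) "f" else "m"
  suffix <- if (sex == "m") "_m" else "_f"
  # free components of the constrained block, by letter
  letters_free <- if (spec$equal_sexes) {
    intersect(c("a", "c", "e"), spec$paths)
  } else {
    sub("_.*", "", intersect(paste0(c("a", "c", "e"), suffix), spec$paths))
  }
  has_am <- !spec$equal_sexes && sex == "m" && "am_prime" %in% spec$paths
  if (has_am && !("a" %in% letters_free)) letters_free <- c("a", letters_free)
  if (!(tolower(comp) %in% letters_free))
    stop("component ", component, " is not free in Model ", spec$id)
  others <- setdiff(letters_free, tolower(comp))
  block_paths <- if (spec$equal_sexes) letters_free
                 else c(paste0(setdiff(letters_free, if (has_am) "zz"),
                               suffix), if (has_am) "am_prime")
  block_paths <- intersect(c(block_paths,
                             if (!spec$equal_sexes)
                               paste0(letters_free, suffix)), spec$paths)
  if (spec$equal_sexes) block_paths <- letters_free
  if (has_am) block_paths <- union(block_paths, "am_prime")
  nuis_paths <- setdiff(spec$paths, block_paths)

  build <- function(phi) {
    t_sd <- phi[1]
    idx <- 2L
    sh <- stats::setNames(numeric(length(letters_free)), letters_free)
    sh[tolower(comp)] <- s
    rem <- 1 - s
    if (length(others) == 1L) {
      sh[others] <- rem
    } else if (length(others) == 2L) {
      u <- phi[idx]; idx <- idx + 1L
      sh[others[1]] <- u * rem; sh[others[2]] <- (1 - u) * rem
    }
    th <- stats::setNames(numeric(spec$n_paths), spec$paths)
    for (l in letters_free) {
      nm <- if (spec$equal_sexes) l else paste0(l, suffix)
      if (nm %in% spec$paths) th[nm] <- t_sd * sqrt(sh[l])
    }
    if (has_am) {   # folded additive share splits into a_m^2 and am'^2
      w <- phi[idx]; idx <- idx + 1L
      nm_a <- paste0("a", suffix)
      if (nm_a %in% spec$paths) th[nm_a] <- t_sd * sqrt(sh["a"] * w)
      th["am_prime"] <- t_sd * sqrt(sh["a"] * (1 - w))
    }
    if (length(nuis_paths))
      th[nuis_paths] <- phi[idx:(idx + length(nuis_paths) - 1L)]
    th
  }
  # start from the fitted solution
  pars_hat <- fit$theta
  blockvar <- function(th) {
    p <- .theta_to_params(th, spec)
    if (sex == "f" || spec$equal_sexes) p$a_f^2 + p$c_f^2 + p$e_f^2
    else p$a_m^2 + p$am_prime^2 + p$c_m^2 + p$e_m^2
  }
  t0 <- sqrt(max(blockvar(pars_hat), 1e-6))
  phi0 <- t0
  if (length(others) == 2L) phi0 <- c(phi0, 0.5)
  if (has_am) phi0 <- c(phi0, 0.8)
  phi0 <- c(phi0, pmax(pars_hat[nuis_paths], 1e-3))
  lower <- c(1e-6, rep(1e-6, length(phi0) - 1 - length(nuis_paths)),
             rep(0, length(nuis_paths)))
  upper <- c(Inf, rep(1 - 1e-6, length(phi0) - 1 - length(nuis_paths)),
             rep(Inf, length(nuis_paths)))
  obj <- function(phi)
    as.numeric(.fiml_neg2ll(.theta_to_params(build(phi), spec), prep))
  list(obj = obj, phi0 = phi0, lower = lower, upper = upper)
}

.profile_min <- function(fit, component, s, warm = NULL) {
  po <- .profile_objective(fit, component, s)
  phi0 <- if (!is.null(warm) && length(warm) == length(po$phi0)) warm
          else po$phi0
  phi0 <- pmin(pmax(phi0, po$lower + 1e-8), ifelse(is.finite(po$upper),
                                                   po$upper - 1e-8, phi0))
  ans <- tryCatch(stats::nlminb(phi0, po$obj, lower = po$lower,
                                upper = po$upper,
                                control = list(rel.tol = 1e-9,
                                               iter.max = 300)),
                  error = function(e) NULL)
  if (is.null(ans)) return(list(val = .BARRIER, par = phi0))
  # one cold restart guards warm starts trapped on a barrier
  ans2 <- tryCatch(stats::nlminb(po$phi0, po$obj, lower = po$lower,
                                 upper = po$upper,
                                 control = list(rel.tol = 1e-9,
                                                iter.max = 300)),
                   error = function(e) NULL)
  if (!is.null(ans2) && ans2$objective < ans$objective) ans <- ans2
  list(val = ans$objective, par = ans$par)
}

#' Profile-likelihood confidence interval for a standardized component
#'
#' Likelihood-based interval: the set of share values whose constrained
#' -2LL lies within `qchisq(level, 1)` (3.84 for 95%) of the minimum.
#' The profile is scanned coarsely on each side of the estimate to
#' bracket the crossing, then refined by bisection with warm-started
#' constrained fits; bounds are clipped to [0, 100].
#'
#' @param fit An `ace_fit`.
#' @param component One of `"A_f"`, `"C_f"`, `"E_f"`, `"A_m"`, `"C_m"`,
#'   `"E_m"` (for Models V/VI the sex suffix is ignored). For Model I the
#'   male additive share profiles the folded `a_m^2 + am_prime^2`.
#' @param level Confidence level, default 0.95.
#' @param grid_n Coarse bracketing points per side (default 8).
#' @return Numeric `c(low, high)` in percent.
#' @export
profile_ci <- function(fit, component, level = 0.95, grid_n = 8) {
  stopifnot(inherits(fit, "ace_fit"))
  crit <- stats::qchisq(level, 1)
  comp <- toupper(substr(component, 1, 1))
  if (!comp %in% colnames(fit$shares))
    stop("unknown component: ", component)
  sexrow <- if (fit$spec$equal_sexes) 1
            else if (grepl("_m$", component, ignore.case = TRUE)) 2 else 1
  s_hat <- fit$shares[sexrow, comp] / 100
  target <- fit$neg2ll + crit

  excess <- local({
    warm <- NULL
    function(s) {
      pm <- .profile_min(fit, component, s, warm)
      warm <<- pm$par
      pm$val - target
    }
  })

  bound <- function(dir) {   # dir = -1 lower, +1 upper
    lim <- if (dir < 0) 0 else 1
    grid <- seq(s_hat, lim, length.out = grid_n + 1)[-1]
    lo_s <- s_hat; f_lo <- -crit
    hit <- NA
    for (s in grid) {
      fs <- excess(min(max(s, 1e-4), 1 - 1e-4))
      if (fs > 0) { hit <- s; f_hi <- fs; break }
      lo_s <- s; f_lo <- fs
    }
    if (is.na(hit)) return(lim)           # profile stays flat to the edge
    a <- lo_s; b <- hit
    for (i in 1:20) {
      m <- (a + b) / 2
      fm <- excess(min(max(m, 1e-4), 1 - 1e-4))
      if (fm > 0) b <- m else a <- m
      if (abs(b - a) < 5e-4) break
    }
    (a + b) / 2
  }

  lo <- bound(-1); hi <- bound(+1)
  100 * c(max(min(lo, hi), 0), min(max(lo, hi), 1))
}
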