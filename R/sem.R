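# Structural equation modelling with full-information maximum likelihood.
#
# The engine uses the RAM parameterization: for the full variable vector v
# (observed then latent), v = A v + u with cov(u) = S and E[u] = m, so the
# implied moments are V = (I-A)^-1 S (I-A)^-T and mu = (I-A)^-1 m, restricted
# to the observed coordinates.  The casewise (FIML) Gaussian log-likelihood is
# accumulated over missing-data patterns using per-pattern sufficient
# statistics, with an analytic gradient so that repeated fits (coverage and
# null-calibration simulations) stay cheap.

MODEL_OPS <- c("=~", "~~", "~")

#' Parse model syntax
#'
#' Accepts lavaan-style syntax restricted to three operators:
#' `f =~ a + b` (factor loadings), `y ~ x1 + x2` (regressions) and
#' `a ~~ b` (covariances / variances).  Lines are separated by newlines or
#' semicolons; `#` starts a comment.
#'
#' @param syntax character scalar or vector of model lines.
#' @return data.frame with columns `lhs`, `op`, `rhs`.
#' @keywords internal
parse_model_syntax <- function(syntax) {
  lines <- unlist(strsplit(paste(syntax, collapse = "\n"), "[\n;]"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    op <- MODEL_OPS[vapply(MODEL_OPS, function(o) grepl(o, ln, fixed = TRUE), logical(1))][1]
    if (is.na(op)) stop("cannot parse model line: '", ln, "'")
    parts <- strsplit(ln, op, fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("cannot parse model line: '", ln, "'")
    lhs <- trimws(parts[1])
    rhs <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
    if (!nzchar(lhs) || any(!nzchar(rhs))) stop("empty variable in line: '", ln, "'")
    for (r in rhs) out[[length(out) + 1L]] <- data.frame(lhs = lhs, op = op, rhs = r)
  }
  do.call(rbind, out)
}

# Full parameter table for one group: every non-zero cell of A, S, m with its
# role, a key used for cross-group equality, whether it is free, and (if fixed)
# its value.
build_partable <- function(pt) {
  latents <- unique(pt$lhs[pt$op == "=~"])
  mentioned <- unique(c(pt$lhs, pt$rhs))
  observed <- setdiff(mentioned, latents)
  indicators <- unique(pt$rhs[pt$op == "=~"])
  if (any(indicators %in% latents)) stop("second-order factors are not supported")
  endo <- unique(pt$lhs[pt$op == "~"])
  if (any(latents %in% endo)) {
    stop("endogenous latent variables are not supported; latents must be exogenous predictors")
  }
  # exogenous set: predictors (or latents) that are never regression outcomes
  # nor indicators; these get free variances and pairwise covariances.
  preds <- unique(pt$rhs[pt$op == "~"])
  exog <- setdiff(union(preds, latents), union(endo, indicators))

  rows <- list()
  add <- function(mat, r, c, free, value, key, role) {
    rows[[length(rows) + 1L]] <<- data.frame(
      mat = mat, row = r, col = c, free = free, value = value,
      key = key, role = role, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(pt))) {
    l <- pt$lhs[i]; o <- pt$op[i]; r <- pt$rhs[i]
    if (o == "=~") add("A", r, l, TRUE, NA_real_, paste0(l, "=~", r), "loading")
    if (o == "~")  add("A", l, r, TRUE, NA_real_, paste0(l, "~", r), "regression")
    if (o == "~~") {
      role <- if (l == r) "variance" else "covariance"
      add("S", l, r, TRUE, NA_real_, paste0(l, "~~", r), role)
    }
  }
  user_s <- vapply(rows, function(x) if (x$mat == "S")
    paste(sort(c(x$row, x$col)), collapse = "|") else "", character(1))
  has_s <- function(a, b) paste(sort(c(a, b)), collapse = "|") %in% user_s
  for (v in observed) if (!has_s(v, v))
    add("S", v, v, TRUE, NA_real_, paste0(v, "~~", v), "variance")
  for (f in latents) if (!has_s(f, f))
    add("S", f, f, FALSE, 1, paste0(f, "~~", f), "lv_variance")
  if (length(exog) > 1L) {
    for (i in seq_len(length(exog) - 1L)) for (j in seq(i + 1L, length(exog))) {
      a <- exog[i]; b <- exog[j]
      if (!has_s(a, b)) add("S", a, b, TRUE, NA_real_, paste0(a, "~~", b), "covariance")
    }
  }
  for (v in observed) add("m", v, "", TRUE, NA_real_, paste0(v, "~1"), "mean")
  tab <- do.call(rbind, rows)
  list(table = tab, observed = observed, latents = latents, exog = exog)
}

# Per-pattern sufficient statistics: index of observed columns, n, mean vector
# and ML (divide-by-n) covariance of the rows sharing a missingness pattern.
pattern_stats <- function(Y) {
  keep <- rowSums(!is.na(Y)) > 0L
  n_dropped <- sum(!keep)
  Y <- Y[keep, , drop = FALSE]
  if (nrow(Y) == 0L) stop("no cases with at least one observed model variable")
  key <- apply(!is.na(Y), 1L, paste, collapse = "")
  pats <- lapply(split(seq_len(nrow(Y)), key), function(idx) {
    obs <- which(!is.na(Y[idx[1], ]))
    Yo <- Y[idx, obs, drop = FALSE]
    n <- nrow(Yo)
    ybar <- colMeans(Yo)
    Yc <- sweep(Yo, 2L, ybar)
    list(obs = obs, n = n, ybar = ybar, S = crossprod(Yc) / n)
  })
  list(patterns = unname(pats), n = nrow(Y), n_dropped = n_dropped,
       complete = length(pats) == 1L && length(pats[[1]]$obs) == ncol(Y))
}

start_values <- function(tab, Y, observed) {
  v_mean <- suppressWarnings(colMeans(Y, na.rm = TRUE))
  v_var <- suppressWarnings(apply(Y, 2L, stats::var, na.rm = TRUE))
  v_var[!is.finite(v_var) | v_var <= 0] <- 1
  v_mean[!is.finite(v_mean)] <- 0
  sds <- sqrt(v_var)
  st <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!tab$free[i]) { st[i] <- tab$value[i]; next }
    st[i] <- switch(tab$role[i],
      loading    = 0.7 * sds[[tab$row[i]]],
      regression = 0,
      variance   = 0.5 * v_var[[tab$row[i]]],
      covariance = 0,
      mean       = v_mean[[tab$row[i]]],
      0)
  }
  st
}

#' Define a structural equation model
#'
#' Prepares a model object holding the parameter table, per-group
#' missing-data-pattern sufficient statistics and start values.  Groups are
#' fitted with group-specific parameters; `constraints` names parameters held
#' equal across groups (shared free parameter).
#'
#' @param syntax model syntax; see [parse_model_syntax()].
#' @param data data.frame containing every observed model variable.
#' @param group optional name of a grouping column in `data`.
#' @param constraints for grouped models, a character vector of equality
#'   constraints: `"regressions"` (all structural paths), `"loadings"`, or
#'   specific parameter keys such as `"peer~mq"` / `"fq=~fc_bond"`.
#' @return an object of class `sem_model`.
#' @export
sem_model <- function(syntax, data, group = NULL, constraints = NULL) {
  pt <- parse_model_syntax(syntax)
  built <- build_partable(pt)
  observed <- built$observed
  missing_cols <- setdiff(observed, names(data))
  if (length(missing_cols))
    stop("data lacks model variables: ", paste(missing_cols, collapse = ", "))
  if (!is.null(group)) {
    if (!group %in% names(data)) stop("grouping column '", group, "' not in data")
    glab <- as.character(data[[group]])
    groups <- sort(unique(glab))
    if (length(groups) < 2L) stop("grouping column has fewer than 2 levels")
  } else {
    glab <- rep("all", nrow(data))
    groups <- "all"
  }
  eq_keys <- character(0)
  if (!is.null(constraints)) {
    tab <- built$table
    for (cn in constraints) {
      eq_keys <- c(eq_keys, switch(cn,
        regressions = tab$key[tab$role == "regression"],
        loadings    = tab$key[tab$role == "loading"],
        {
          if (!cn %in% tab$key) stop("constraint refers to unknown parameter: ", cn)
          cn
        }))
    }
    eq_keys <- unique(eq_keys)
  }

  per_group <- list()
  free_ids <- integer(0)      # map rows across groups to global free ids
  shared_id <- new.env(parent = emptyenv())
  next_id <- 0L
  start_acc <- list()
  for (g in groups) {
    Yg <- as.matrix(data[glab == g, observed, drop = FALSE])
    storage.mode(Yg) <- "double"
    tab <- built$table
    ids <- rep(NA_integer_, nrow(tab))
    for (i in seq_len(nrow(tab))) {
      if (!tab$free[i]) next
      if (tab$key[i] %in% eq_keys) {
        if (is.null(shared_id[[tab$key[i]]])) {
          next_id <- next_id + 1L
          shared_id[[tab$key[i]]] <- next_id
        }
        ids[i] <- shared_id[[tab$key[i]]]
      } else {
        next_id <- next_id + 1L
        ids[i] <- next_id
      }
    }
    st <- start_values(tab, Yg, observed)
    for (i in seq_len(nrow(tab))) if (!is.na(ids[i])) {
      id <- as.character(ids[i])
      start_acc[[id]] <- c(start_acc[[id]], st[i])
    }
    per_group[[g]] <- list(table = tab, ids = ids,
                           stats = pattern_stats(Yg), label = g)
  }
  start <- vapply(as.character(seq_len(next_id)), function(id)
    mean(start_acc[[id]]), numeric(1))

  nv <- length(observed) + length(built$latents)
  vars <- c(observed, built$latents)
  structure(list(
    syntax = syntax, partable = built$table, observed = observed,
    latents = built$latents, exog = built$exog, vars = vars, nv = nv,
    groups = groups, per_group = per_group, nfree = next_id, start = start,
    constraints = eq_keys, group_col = group
  ), class = "sem_model")
}

# Fill A, S, m for one group at parameter vector par.
ram_matrices <- function(model, par, g) {
  pg <- model$per_group[[g]]
  tab <- pg$table
  vars <- model$vars
  nv <- model$nv
  A <- matrix(0, nv, nv, dimnames = list(vars, vars))
  S <- matrix(0, nv, nv, dimnames = list(vars, vars))
  m <- stats::setNames(numeric(nv), vars)
  vals <- ifelse(is.na(pg$ids), tab$value, par[pg$ids])
  for (i in seq_len(nrow(tab))) {
    v <- vals[i]
    if (tab$mat[i] == "A") A[tab$row[i], tab$col[i]] <- v
    else if (tab$mat[i] == "S") {
      S[tab$row[i], tab$col[i]] <- v
      S[tab$col[i], tab$row[i]] <- v
    } else m[tab$row[i]] <- v
  }
  IA <- solve(diag(nv) - A)
  V <- IA %*% S %*% t(IA)
  mu <- as.vector(IA %*% m)
  oi <- seq_along(model$observed)
  list(A = A, S = S, m = m, IA = IA, V = V,
       Sigma = V[oi, oi, drop = FALSE], mu = mu[oi])
}

# loglik of one group's patterns under (mu, Sigma); optionally accumulate the
# gradient pieces dl/dSigma (Lam) and dl/dmu (gmu) over observed coordinates.
pattern_loglik <- function(stats, mu, Sigma, want_grad = FALSE) {
  p_all <- length(mu)
  ll <- 0
  Lam <- if (want_grad) matrix(0, p_all, p_all) else NULL
  gmu <- if (want_grad) numeric(p_all) else NULL
  for (pat in stats$patterns) {
    o <- pat$obs
    Sg <- Sigma[o, o, drop = FALSE]
    R <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(R)) return(list(ll = -Inf))
    p <- length(o)
    d <- pat$ybar - mu[o]
    Sinv <- chol2inv(R)
    quad <- sum(Sinv * pat$S) + drop(t(d) %*% Sinv %*% d)
    ll <- ll - pat$n / 2 * (p * log(2 * pi) + 2 * sum(log(diag(R))) + quad)
    if (want_grad) {
      M <- pat$S + tcrossprod(d)
      Lam[o, o] <- Lam[o, o] + pat$n / 2 * (Sinv %*% M %*% Sinv - Sinv)
      gmu[o] <- gmu[o] + pat$n * as.vector(Sinv %*% d)
    }
  }
  list(ll = ll, Lam = Lam, gmu = gmu)
}

#' FIML log-likelihood
#'
#' Casewise Gaussian log-likelihood of the data under the model-implied mean
#' and covariance at `par`, summed over missing-data patterns (and groups).
#' With no missing data this equals the complete-data ML log-likelihood.
#'
#' @param model a [sem_model()] object.
#' @param par free-parameter vector; defaults to the start values.
#' @return scalar log-likelihood (`-Inf` if the implied covariance of any
#'   pattern is not positive definite).
#' @export
fiml_loglik <- function(model, par = model$start) {
  ll <- 0
  for (g in model$groups) {
    im <- ram_matrices(model, par, g)
    r <- pattern_loglik(model$per_group[[g]]$stats, im$mu, im$Sigma)
    if (!is.finite(r$ll)) return(-Inf)
    ll <- ll + r$ll
  }
  ll
}

# Analytic gradient of fiml_loglik; zero vector at non-PD points (the
# optimizer only sees those through the penalized objective).
fiml_gradient <- function(model, par) {
  grad <- numeric(model$nfree)
  oi <- seq_along(model$observed)
  nv <- model$nv
  for (g in model$groups) {
    im <- ram_matrices(model, par, g)
    r <- pattern_loglik(model$per_group[[g]]$stats, im$mu, im$Sigma, want_grad = TRUE)
    if (!is.finite(r$ll)) return(grad)
    G <- matrix(0, nv, nv); G[oi, oi] <- r$Lam
    gm <- numeric(nv); gm[oi] <- r$gmu
    IA <- im$IA
    tIA_G <- t(IA) %*% G
    dA <- 2 * tIA_G %*% IA %*% im$S %*% t(IA) +
      (t(IA) %*% gm) %*% t(as.vector(IA %*% im$m))
    dS_full <- tIA_G %*% IA
    dm <- as.vector(t(IA) %*% gm)
    pg <- model$per_group[[g]]
    tab <- pg$table
    vi <- match(tab$row, model$vars)
    ci <- match(tab$col, model$vars)
    for (i in seq_len(nrow(tab))) {
      id <- pg$ids[i]
      if (is.na(id)) next
      gcontrib <- if (tab$mat[i] == "A") dA[vi[i], ci[i]]
      else if (tab$mat[i] == "S") {
        if (vi[i] == ci[i]) dS_full[vi[i], vi[i]] else 2 * dS_full[vi[i], ci[i]]
      } else dm[vi[i]]
      grad[id] <- grad[id] + gcontrib
    }
  }
  grad
}

PENALTY <- 1e10

sem_objective <- function(model) {
  list(
    fn = function(p) {
      ll <- fiml_loglik(model, p)
      if (!is.finite(ll)) PENALTY else -ll
    },
    gr = function(p) -fiml_gradient(model, p)
  )
}

#' Fit a structural equation model by FIML
#'
#' Maximizes the casewise Gaussian likelihood with a quasi-Newton optimizer
#' and multiple jittered starts.  Standard errors come from the observed
#' information (numeric Jacobian of the analytic gradient); chi-square is
#' measured against the saturated (EM) Gaussian fit, with CFI against the
#' independence baseline and SRMR on standardized covariance residuals.
#'
#' @param model a [sem_model()] object, or model syntax (then `data` is
#'   required).
#' @param data data.frame, used when `model` is syntax.
#' @param group,constraints passed to [sem_model()] when `model` is syntax.
#' @param starts number of optimizer starts (first is unjittered).
#' @param se compute standard errors / covariance matrix (set `FALSE` inside
#'   large simulation loops that only need point estimates and logliks).
#' @param start_jitter_seed seed offset for the jittered starts.
#' @return object of class `sem_fit`: parameter table with estimates, SEs and
#'   95% CIs, `loglik`, `npar`, `df`, `chi_square`, `cfi`, `srmr`,
#'   `n_per_group`, per-group implied moments.
#' @export
fit_sem <- function(model, data = NULL, group = NULL, constraints = NULL,
                    starts = 3L, se = TRUE, start_jitter_seed = 1L) {
  if (!inherits(model, "sem_model")) {
    if (is.null(data)) stop("supply 'data' when 'model' is syntax")
    model <- sem_model(model, data, group = group, constraints = constraints)
  }
  obj <- sem_objective(model)
  best <- NULL
  trace <- character(0)
  for (s in seq_len(starts)) {
    p0 <- model$start
    if (s > 1L) {
      rs <- local({
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        set.seed(start_jitter_seed * 1000L + s)
        jit <- p0 + stats::rnorm(length(p0), 0, 0.1 * pmax(abs(p0), 0.2))
        if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
          rm(".Random.seed", envir = globalenv())
        jit
      })
      p0 <- rs
    }
    ans <- stats::nlminb(p0, obj$fn, gradient = obj$gr,
                         control = list(iter.max = 1000L, eval.max = 3000L))
    trace <- c(trace, sprintf("start %d: objective %.6f, convergence %d (%s)",
                              s, ans$objective, ans$convergence, ans$message))
    ok <- is.finite(ans$objective) && ans$objective < PENALTY / 2
    if (ok && (is.null(best) || ans$objective < best$objective - 1e-8)) best <- ans
  }
  if (is.null(best))
    stop("SEM optimization failed to converge:\n", paste(trace, collapse = "\n"))
  par <- best$par
  ll <- -best$objective

  vcov <- NULL; separ <- rep(NA_real_, model$nfree)
  if (se) {
    H <- gradient_jacobian(function(p) -fiml_gradient(model, p), par)
    H <- (H + t(H)) / 2
    vcov <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(vcov) || any(!is.finite(diag(vcov)))) {
      ev <- eigen(H, symmetric = TRUE)
      pos <- ev$values > max(ev$values) * 1e-10
      vcov <- ev$vectors[, pos, drop = FALSE] %*%
        (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
    }
    separ <- sqrt(pmax(diag(vcov), 0))
  }

  # fit measures against saturated & independence baselines
  ll_sat <- 0; ll_ind <- 0; df_ind <- 0L; nmom <- 0L
  srmr_g <- numeric(0)
  implied <- list()
  n_per_group <- integer(0)
  for (g in model$groups) {
    st <- model$per_group[[g]]$stats
    n_per_group[g] <- st$n
    p <- length(model$observed)
    sat <- saturated_gaussian(st, p)
    ll_sat <- ll_sat + sat$loglik
    ll_ind <- ll_ind + independence_loglik(st, p)
    df_ind <- df_ind + (p * (p - 1L)) %/% 2L
    nmom <- nmom + (p * (p + 1L)) %/% 2L + p
    im <- ram_matrices(model, par, g)
    implied[[g]] <- im
    sdd <- sqrt(diag(sat$Sigma))
    res <- (sat$Sigma - im$Sigma) / tcrossprod(sdd)
    srmr_g <- c(srmr_g, sqrt(mean(res[lower.tri(res, diag = TRUE)]^2)))
  }
  df <- as.integer(nmom - model$nfree)
  chi_m <- max(2 * (ll_sat - ll), 0)
  chi_b <- max(2 * (ll_sat - ll_ind), 0)
  cfi <- 1 - max(chi_m - df, 0) / max(chi_m - df, chi_b - df_ind, .Machine$double.eps)

  # Heywood check: negative residual variances
  heywood <- FALSE
  for (g in model$groups) {
    pg <- model$per_group[[g]]
    vals <- ifelse(is.na(pg$ids), pg$table$value, par[pg$ids])
    heywood <- heywood || any(vals[pg$table$role == "variance"] < 0)
  }

  est_table <- do.call(rbind, lapply(model$groups, function(g) {
    pg <- model$per_group[[g]]
    vals <- ifelse(is.na(pg$ids), pg$table$value, par[pg$ids])
    ses <- ifelse(is.na(pg$ids), NA_real_, separ[pg$ids])
    data.frame(group = g, key = pg$table$key, role = pg$table$role,
               mat = pg$table$mat, row = pg$table$row, col = pg$table$col,
               free_id = pg$ids, est = vals, se = ses,
               ci_lower = vals - 1.959964 * ses, ci_upper = vals + 1.959964 * ses,
               stringsAsFactors = FALSE)
  }))

  structure(list(
    model = model, par = par, loglik = ll, npar = model$nfree, df = df,
    chi_square = chi_m, cfi = cfi, srmr = mean(srmr_g), vcov = vcov,
    estimates = est_table, implied = implied, n_per_group = n_per_group,
    heywood = heywood, convergence = best$convergence, trace = trace
  ), class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("SEM fit by FIML:", x$npar, "free parameters, df =", x$df, "\n")
  cat(sprintf("  loglik = %.3f, chi-square = %.3f, CFI = %.3f, SRMR = %.4f\n",
              x$loglik, x$chi_square, x$cfi, x$srmr))
  cat("  n per group:", paste(names(x$n_per_group), x$n_per_group,
                              sep = "=", collapse = ", "), "\n")
  if (x$heywood) cat("  WARNING: Heywood case (negative residual variance)\n")
  invisible(x)
}

# central-difference Jacobian of a vector-valued function (used for the
# observed information and for delta-method standardized CIs)
gradient_jacobian <- function(fn, par, h = NULL) {
  k <- length(par)
  if (is.null(h)) h <- 1e-5 * pmax(abs(par), 1)
  f0 <- fn(par)
  J <- matrix(0, length(f0), k)
  for (i in seq_len(k)) {
    up <- par; up[i] <- up[i] + h[i]
    dn <- par; dn[i] <- dn[i] - h[i]
    J[, i] <- (fn(up) - fn(dn)) / (2 * h[i])
  }
  J
}

# Saturated Gaussian MLE under ignorable missingness (EM on pattern sufficient
# statistics); closed-form when the data are complete.
saturated_gaussian <- function(stats, p, max_iter = 500L, tol = 1e-9) {
  if (stats$complete) {
    pat <- stats$patterns[[1]]
    mu <- pat$ybar; Sigma <- pat$S
    ll <- pattern_loglik(stats, mu, Sigma)$ll
    return(list(mu = mu, Sigma = Sigma, loglik = ll, iter = 0L))
  }
  # init from available-case moments
  mu <- numeric(p); vv <- numeric(p); nv <- numeric(p)
  for (pat in stats$patterns) {
    o <- pat$obs
    mu[o] <- mu[o] + pat$n * pat$ybar
    vv[o] <- vv[o] + pat$n * (diag(pat$S) + pat$ybar^2)
    nv[o] <- nv[o] + pat$n
  }
  mu <- mu / pmax(nv, 1)
  Sigma <- diag(pmax(vv / pmax(nv, 1) - mu^2, 1e-6), p)
  ll_old <- -Inf
  n <- stats$n
  for (it in seq_len(max_iter)) {
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    for (pat in stats$patterns) {
      o <- pat$obs; m <- setdiff(seq_len(p), o)
      nk <- pat$n
      sum_o <- nk * pat$ybar
      S2_o <- nk * (pat$S + tcrossprod(pat$ybar))   # sum y_o y_o'
      T1[o] <- T1[o] + sum_o
      T2[o, o] <- T2[o, o] + S2_o
      if (length(m)) {
        B <- Sigma[m, o, drop = FALSE] %*% solve(Sigma[o, o, drop = FALSE])
        C <- Sigma[m, m, drop = FALSE] - B %*% Sigma[o, m, drop = FALSE]
        d_sum <- sum_o - nk * mu[o]
        mhat_sum <- nk * mu[m] + as.vector(B %*% d_sum)
        T1[m] <- T1[m] + mhat_sum
        # sum over rows of yhat_m y_o' and yhat_m yhat_m'
        Do <- S2_o - tcrossprod(sum_o, mu[o]) - tcrossprod(mu[o], sum_o) +
          nk * tcrossprod(mu[o])                     # sum d d'
        cross_mo <- tcrossprod(mu[m], sum_o) + B %*% (S2_o - tcrossprod(mu[o], sum_o))
        T2[m, o] <- T2[m, o] + cross_mo
        T2[o, m] <- T2[o, m] + t(cross_mo)
        mm <- nk * tcrossprod(mu[m]) + tcrossprod(mu[m], as.vector(B %*% d_sum)) +
          tcrossprod(as.vector(B %*% d_sum), mu[m]) + B %*% Do %*% t(B) + nk * C
        T2[m, m] <- T2[m, m] + mm
      }
    }
    mu <- T1 / n
    Sigma <- T2 / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- pattern_loglik(stats, mu, Sigma)$ll
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sigma, loglik = ll, iter = it)
}

# independence (diagonal covariance) baseline: per-variable univariate MLEs
independence_loglik <- function(stats, p) {
  s1 <- numeric(p); s2 <- numeric(p); nv <- numeric(p)
  for (pat in stats$patterns) {
    o <- pat$obs
    s1[o] <- s1[o] + pat$n * pat$ybar
    s2[o] <- s2[o] + pat$n * (diag(pat$S) + pat$ybar^2)
    nv[o] <- nv[o] + pat$n
  }
  ll <- 0
  for (v in seq_len(p)) {
    if (nv[v] == 0) next
    m <- s1[v] / nv[v]
    va <- max(s2[v] / nv[v] - m^2, 1e-12)
    ll <- ll - nv[v] / 2 * (log(2 * pi) + log(va) + 1)
  }
  ll
}

#' Standardized solution
#'
#' Standardizes estimates using model-implied total variances: a path y ~ x
#' becomes beta * sd(x)/sd(y); covariances become correlations.  Delta-method
#' 95% CIs are computed from the fit's parameter covariance matrix.
#'
#' @param fit a [fit_sem()] result.
#' @return the estimate table with `std`, `std_se`, `std_ci_lower`,
#'   `std_ci_upper` columns added.
#' @export
standardized_solution <- function(fit) {
  model <- fit$model
  std_of_par <- function(par) {
    out <- numeric(0)
    for (g in model$groups) {
      im <- ram_matrices(model, par, g)
      sdv <- sqrt(pmax(diag(im$V), .Machine$double.eps))
      names(sdv) <- model$vars
      pg <- model$per_group[[g]]
      tab <- pg$table
      vals <- ifelse(is.na(pg$ids), tab$value, par[pg$ids])
      s <- vals
      for (i in seq_len(nrow(tab))) {
        if (tab$mat[i] == "A") {
          s[i] <- vals[i] * sdv[[tab$col[i]]] / sdv[[tab$row[i]]]
        } else if (tab$mat[i] == "S" && tab$row[i] != tab$col[i]) {
          s[i] <- vals[i] / (sdv[[tab$row[i]]] * sdv[[tab$col[i]]])
        } else if (tab$mat[i] == "S") {
          s[i] <- vals[i] / (sdv[[tab$row[i]]]^2)   # proportion of total variance
        }
      }
      out <- c(out, s)
    }
    out
  }
  std <- std_of_par(fit$par)
  tab <- fit$estimates
  tab$std <- std
  if (!is.null(fit$vcov)) {
    J <- gradient_jacobian(std_of_par, fit$par, h = 1e-6 * pmax(abs(fit$par), 1))
    vs <- rowSums((J %*% fit$vcov) * J)
    tab$std_se <- sqrt(pmax(vs, 0))
    free <- !is.na(tab$free_id)
    tab$std_se[!free] <- NA_real_
    tab$std_ci_lower <- tab$std - 1.959964 * tab$std_se
    tab$std_ci_upper <- tab$std + 1.959964 * tab$std_se
  }
  tab
}

#' Multi-group SEM with equality constraints
#'
#' The free model is estimated as independent per-group fits (its
#' log-likelihood is the sum of group log-likelihoods, equivalent to a joint
#' fit with no shared parameters); the constrained model shares the tagged
#' parameters across groups and is warm-started from the free solutions.
#' Compare the two with [lrt()].
#'
#' @param syntax model syntax.
#' @param data data.frame including the grouping column.
#' @param group name of the grouping column.
#' @param constraints which parameters to equate in the constrained model
#'   (default all structural regressions, as in invariance tests of path
#'   coefficients); an empty vector gives a constrained model identical to
#'   the free one.
#' @param ... passed to [fit_sem()].
#' @return list with `free` (class `sem_fit_pooled`: `loglik`, `npar`,
#'   per-group `fits`) and `constrained` (`sem_fit`).
#' @export
fit_multigroup <- function(syntax, data, group, constraints = "regressions", ...) {
  if (!group %in% names(data)) stop("grouping column '", group, "' not in data")
  glab <- as.character(data[[group]])
  groups <- sort(unique(glab))
  if (length(groups) < 2L) stop("grouping column has fewer than 2 levels")
  group_fits <- lapply(groups, function(g)
    fit_sem(sem_model(syntax, data[glab == g, , drop = FALSE]), ...))
  names(group_fits) <- groups
  free <- structure(list(
    loglik = sum(vapply(group_fits, `[[`, numeric(1), "loglik")),
    npar = sum(vapply(group_fits, `[[`, integer(1), "npar")),
    fits = group_fits,
    n_per_group = vapply(group_fits, function(f) f$n_per_group[[1]], numeric(1))
  ), class = "sem_fit_pooled")

  con_model <- sem_model(syntax, data, group = group, constraints = constraints)
  # warm start: per-group solutions, averaging the equality-constrained ones
  st <- numeric(con_model$nfree)
  cnt <- numeric(con_model$nfree)
  for (g in groups) {
    pg <- con_model$per_group[[g]]
    gf <- group_fits[[g]]
    gsol <- gf$estimates$est
    ids <- pg$ids
    for (i in seq_along(ids)) if (!is.na(ids[i])) {
      st[ids[i]] <- st[ids[i]] + gsol[i]
      cnt[ids[i]] <- cnt[ids[i]] + 1
    }
  }
  con_model$start <- ifelse(cnt > 0, st / pmax(cnt, 1), con_model$start)
  fit_con <- fit_sem(con_model, ...)
  list(free = free, constrained = fit_con)
}

#' Likelihood-ratio test of nested SEM fits
#'
#' @param fit_free the less constrained fit.
#' @param fit_constrained the nested, more constrained fit.
#' @return list with `stat` (= -2 * (ll_c - ll_f)), `df` (difference in free
#'   parameter counts) and `p` (chi-square upper tail).
#' @export
lrt <- function(fit_free, fit_constrained) {
  stat <- -2 * (fit_constrained$loglik - fit_free$loglik)
  if (stat < -1e-6)
    stop("constrained log-likelihood exceeds free log-likelihood (", stat,
         "); a fit failed to converge")
  stat <- max(stat, 0)
  df <- fit_free$npar - fit_constrained$npar
  if (df < 0) stop("models are not nested: constrained fit has more parameters")
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(stat = stat, df = df, p = p)
}

#' Structural model syntax for the resistance path diagram
#'
#' Two latent parenting-quality factors (father, mother) with four indicators
#' each, observed parental monitoring, three mediators (peer drinking, partner
#' drinking, social competence) regressed on the three parenting predictors,
#' and the resistance outcome regressed on all six upstream variables.
#' Mediator disturbances covary freely, as do the exogenous predictors.
#'
#' @param outcome name of the resistance outcome column.
#' @return model syntax string.
#' @export
resistance_model_syntax <- function(outcome = "resist") {
  paste(c(
    "fq =~ fc_bond + fc_close + fc_comm + fc_inv",
    "mq =~ mc_bond + mc_close + mc_comm + mc_inv",
    "peer ~ fq + mq + monitoring",
    "partner ~ fq + mq + monitoring",
    "soccomp ~ fq + mq + monitoring",
    paste0(outcome, " ~ fq + mq + monitoring + peer + partner + soccomp"),
    "peer ~~ partner",
    "peer ~~ soccomp",
    "partner ~~ soccomp"
  ), collapse = "\n")
}
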