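#' Forward/backward nonequilibrium work set
#'
#' Sign convention: `forward` is the work of coupling the solute into the
#' solvent (decoupled -> solvated); `backward` is the work measured along
#' the reverse transition (solvated -> decoupled). Under this convention
#' the Crooks fluctuation theorem reads
#' \eqn{P_F(W)/P_R(-W) = \exp[(W - \Delta G)/k_BT]} and a dissipation-free
#' process has `forward == dg` and `backward == -dg`.
#'
#' @param forward numeric vector of forward work values (kJ mol^-1)
#' @param backward numeric vector of reverse-transition work values
#'   (kJ mol^-1)
#' @param temperature temperature in K
#' @return object of class `work_set`
#' @export
work_set <- function(forward, backward, temperature = 300) {
  stopifnot(length(forward) > 0L, length(backward) > 0L,
            all(is.finite(forward)), all(is.finite(backward)),
            temperature > 0)
  structure(list(forward = as.numeric(forward),
                 backward = as.numeric(backward),
                 temperature = temperature),
            class = "work_set")
}

#' Read a work set from plain-text files
#'
#' Each file holds one work value per line (kJ mol^-1); lines starting
#' with `#` or `@` are skipped (xvg-style headers).
#'
#' @param forward_file,backward_file file paths
#' @param temperature temperature in K
#' @return a [work_set()]
#' @export
read_work_set <- function(forward_file, backward_file, temperature = 300) {
  rd <- function(f) {
    ln <- readLines(f)
    ln <- ln[!grepl("^\\s*[#@]", ln) & nzchar(trimws(ln))]
    vals <- suppressWarnings(as.numeric(vapply(strsplit(trimws(ln), "\\s+"),
                                               function(t) t[length(t)], "")))
    if (any(is.na(vals))) stop("non-numeric work value in ", f)
    vals
  }
  work_set(rd(forward_file), rd(backward_file), temperature)
}

# Bennett/Shirts ML balance function; monotone increasing in dg
.bar_fn <- function(dg, wf, wr, beta, M) {
  sum(stats::plogis(-(M + beta * (wf - dg)))) -
    sum(stats::plogis(-(-M + beta * (wr + dg))))
}

#' Maximum-likelihood free energy from nonequilibrium work distributions
#'
#' Solves the Bennett acceptance-ratio self-consistent equation -- the
#' maximum-likelihood estimator implied by the Crooks fluctuation theorem
#' for bidirectional work data:
#' \deqn{\sum_{i=1}^{n_F} f\!\big(M + \beta(W^F_i - \Delta G)\big) =
#'       \sum_{j=1}^{n_R} f\!\big(-M + \beta(W^R_j + \Delta G)\big)}
#' with \eqn{f} the Fermi function and \eqn{M = \ln(n_F/n_R)}. The root is
#' bracketed on `[min(W) - 50, max(W) + 50]` kJ mol^-1 (expanded if
#' needed) and solved by bisection to 1e-8. The standard error comes from
#' bootstrap resampling of both directions.
#'
#' @param work a [work_set()]
#' @param n_boot number of bootstrap resamples (default 1000)
#' @param seed RNG seed for the bootstrap
#' @return list of class `fe_estimate`: `dg`, `se`, `n_forward`,
#'   `n_backward`, `temperature`, `convention`, `overlap`,
#'   `divergence_warning`
#' @export
ml_estimate <- function(work, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(work, "work_set"))
  wf <- work$forward
  wr <- work$backward
  if (length(wf) < 10L || length(wr) < 10L) {
    stop("need at least 10 work values in each direction")
  }
  beta <- 1 / (.KB * work$temperature)
  M <- log(length(wf) / length(wr))
  solve_dg <- function(wf, wr) {
    lo <- min(c(wf, -wr)) - 50
    hi <- max(c(wf, -wr)) + 50
    tries <- 0L
    while (.bar_fn(lo, wf, wr, beta, M) * .bar_fn(hi, wf, wr, beta, M) > 0) {
      lo <- lo - 200; hi <- hi + 200; tries <- tries + 1L
      if (tries > 10L) stop("BAR root not bracketed after interval expansion")
    }
    stats::uniroot(.bar_fn, c(lo, hi), wf = wf, wr = wr, beta = beta, M = M,
                   tol = 1e-8)$root
  }
  dg <- solve_dg(wf, wr)
  # forward and negated-backward distributions must overlap for the
  # estimator to be informative
  rngs <- c(max(min(wf), min(-wr)), min(max(wf), max(-wr)))
  span <- max(c(wf, -wr)) - min(c(wf, -wr))
  overlap <- if (span == 0) 1 else max(0, (rngs[2] - rngs[1]) / span)
  diverged <- overlap < 0.01 && stats::sd(c(wf, -wr)) > 0
  boot <- numeric(n_boot)
  if (n_boot > 0L) {
    old <- .restore_seed(seed)
    on.exit(old(), add = TRUE)
    for (b in seq_len(n_boot)) {
      boot[b] <- solve_dg(sample(wf, replace = TRUE),
                          sample(wr, replace = TRUE))
    }
  }
  structure(list(
    dg = dg,
    se = if (n_boot > 0L) stats::sd(boot) else NA_real_,
    n_forward = length(wf), n_backward = length(wr),
    temperature = work$temperature,
    convention = "forward = coupling work; backward = reverse-transition work",
    overlap = overlap, divergence_warning = diverged
  ), class = "fe_estimate")
}

# set the RNG seed, returning a restorer for the previous state
.restore_seed <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

#' @export
print.fe_estimate <- function(x, ...) {
  cat(sprintf("fe_estimate: dG = %.3f +/- %.3f kJ mol-1 (nF = %d, nR = %d, T = %g K)\n",
              x$dg, x$se, x$n_forward, x$n_backward, x$temperature))
  if (isTRUE(x$divergence_warning)) {
    cat("  WARNING: forward/backward distributions barely overlap\n")
  }
  invisible(x)
}

#' Transfer free energy between two solvation estimates
#'
#' \eqn{\Delta\Delta G_{S1 \to S2} = \Delta G_{\emptyset \to S2} -
#' \Delta G_{\emptyset \to S1}}; uncertainty by quadrature.
#'
#' @param dg_s2 solvation estimate in the target solvent
#' @param dg_s1 solvation estimate in the source solvent
#' @return an `fe_estimate` for the transfer
#' @export
ddg <- function(dg_s2, dg_s1) {
  stopifnot(inherits(dg_s2, "fe_estimate"), inherits(dg_s1, "fe_estimate"))
  if (dg_s2$temperature != dg_s1$temperature) {
    stop("temperature mismatch: ", dg_s2$temperature, " vs ", dg_s1$temperature)
  }
  structure(list(
    dg = dg_s2$dg - dg_s1$dg,
    se = sqrt(dg_s2$se^2 + dg_s1$se^2),
    n_forward = NA_integer_, n_backward = NA_integer_,
    temperature = dg_s2$temperature,
    convention = "ddG = dG(S2) - dG(S1)",
    overlap = NA_real_, divergence_warning = FALSE
  ), class = "fe_estimate")
}

#' Partition coefficient from a water-to-octanol transfer free energy
#'
#' \eqn{\log P = -\Delta\Delta G_{W \to O} / (\ln 10 \cdot RT)} under the
#' default convention (hydrophilic compounds come out negative). The
#' convention flag flips the sign and is recorded in the result.
#'
#' @param ddg_w_to_o transfer free energy water -> octanol (kJ mol^-1)
#' @param temperature temperature in K
#' @param sign_convention `"hydrophilic_negative"` (default) or
#'   `"hydrophilic_positive"`
#' @return list: `logp`, `temperature`, `sign_convention`
#' @export
logp <- function(ddg_w_to_o, temperature = 300,
                 sign_convention = c("hydrophilic_negative", "hydrophilic_positive")) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(temperature > 0)
  v <- -ddg_w_to_o / (log(10) * .KB * temperature)
  if (sign_convention == "hydrophilic_positive") v <- -v
  list(logp = v, temperature = temperature, sign_convention = sign_convention)
}
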