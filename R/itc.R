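# Single-site isothermal titration calorimetry: simulation and fitting.
#
# Total cell concentrations follow the MicroCal perfusion convention for
# an overfilled cell of working volume V0 after cumulative injected
# volume dV:
#     [M]_t = M0 * (1 - dV/(2 V0)) / (1 + dV/(2 V0))
#     [X]_t = X0 * (dV/V0)        / (1 + dV/(2 V0))
# The bound fraction comes from the single-site quadratic (Wiseman
# isotherm); cumulative heat
#     Q(i) = N [M]_t dH V0 / 2 * (b - sqrt(b^2 - 4 Xr))
# with Xr = [X]_t / (N [M]_t) and b = 1 + Xr + 1/(N Ka [M]_t), and the
# per-injection (measured) heat corrects for the liquid displaced into
# the overflow:
#     dq(i) = Q(i) - Q(i-1) + (dV_i/V0) * (Q(i) + Q(i-1)) / 2.

#' Construct an ITC titration protocol
#'
#' Defaults follow a typical small-cell titration: 19 injections of
#' 2.0 ul of 200 uM ligand into 204.4 ul of 20 uM macromolecule at 25 C.
#'
#' @param cellVolume working cell volume in ul.
#' @param cellConc macromolecule concentration (M).
#' @param syringeConc ligand concentration (M).
#' @param injectionVolumes per-injection volumes in ul.
#' @param temperature temperature in Celsius.
#' @param heats optional per-injection heats (ucal).
#' @return an \linkS4class{ITCExperiment}.
#' @export
itcProtocol <- function(cellVolume = 204.4, cellConc = 20e-6,
                        syringeConc = 200e-6,
                        injectionVolumes = rep(2.0, 19),
                        temperature = 25, heats = numeric(0)) {
  new("ITCExperiment", cellVolume = cellVolume, cellConc = cellConc,
      syringeConc = syringeConc, injectionVolumes = injectionVolumes,
      temperature = temperature, heats = heats)
}

#' Construct single-site model parameters
#'
#' @param N stoichiometry (sites per macromolecule).
#' @param Ka association constant (1/M). Exactly one of \code{Ka} and
#'   \code{kdNano} must be given.
#' @param dH binding enthalpy (cal/mol).
#' @param baseline per-injection heat offset (ucal).
#' @param kdNano dissociation constant in nM (alternative to \code{Ka}).
#' @return an \linkS4class{ITCModelParams}.
#' @export
itcModelParams <- function(N = 1, Ka = NULL, dH = -10000, baseline = 0,
                           kdNano = NULL) {
  .stopIfNot(xor(is.null(Ka), is.null(kdNano)),
             "give exactly one of Ka and kdNano")
  if (is.null(Ka)) Ka <- 1e9 / kdNano
  new("ITCModelParams", N = N, Ka = Ka, dH = dH, baseline = baseline)
}

#' Predicted per-injection heats of the single-site model
#'
#' @param params an \linkS4class{ITCModelParams}.
#' @param protocol an \linkS4class{ITCExperiment} (heats ignored).
#' @return numeric per-injection heats in ucal (baseline included).
#' @export
predictHeats <- function(params, protocol) {
  .itcHeats(params@N, params@Ka, params@dH, params@baseline, protocol)
}

.itcCumulative <- function(N, Ka, dH, protocol) {
  V0 <- protocol@cellVolume * 1e-6 * 1e-3            # ul -> L
  dV <- protocol@injectionVolumes * 1e-6 * 1e-3
  cum <- cumsum(dV)
  Mt <- protocol@cellConc * (1 - cum / (2 * V0)) / (1 + cum / (2 * V0))
  Xt <- protocol@syringeConc * (cum / V0) / (1 + cum / (2 * V0))
  Xr <- Xt / (N * Mt)
  b <- 1 + Xr + 1 / (N * Ka * Mt)
  Q <- N * Mt * dH * V0 / 2 * (b - sqrt(pmax(b^2 - 4 * Xr, 0)))   # cal
  list(Q = Q, dV = dV, V0 = V0)
}

.itcHeats <- function(N, Ka, dH, baseline, protocol) {
  cm <- .itcCumulative(N, Ka, dH, protocol)
  Qprev <- c(0, cm$Q[-length(cm$Q)])
  dq <- cm$Q - Qprev + (cm$dV / cm$V0) * (cm$Q + Qprev) / 2
  dq * 1e6 + baseline                                  # ucal
}

#' Simulate a single-site ITC titration
#'
#' Deterministic given the seed; Gaussian noise of standard deviation
#' \code{noiseSd} (ucal) is added per injection. Use
#' \code{relativeNoise} to specify noise as a fraction of the largest
#' clean injection heat instead.
#'
#' @param params an \linkS4class{ITCModelParams}.
#' @param protocol an \linkS4class{ITCExperiment}.
#' @param noiseSd Gaussian noise SD in ucal (default 0).
#' @param relativeNoise if given, overrides \code{noiseSd} with this
#'   fraction of max(|clean heat|).
#' @param seed integer RNG seed (optional).
#' @return an \linkS4class{ITCExperiment} with heats filled in.
#' @examples
#' sim <- simulateTitration(itcModelParams(kdNano = 65), itcProtocol(),
#'                          relativeNoise = 0.02, seed = 1)
#' injectionHeats(sim)
#' @export
simulateTitration <- function(params, protocol = itcProtocol(),
                              noiseSd = 0, relativeNoise = NULL,
                              seed = NULL) {
  clean <- .itcHeats(params@N, params@Ka, params@dH, params@baseline,
                     protocol)
  if (!is.null(relativeNoise))
    noiseSd <- relativeNoise * max(abs(clean - params@baseline))
  if (!is.null(seed)) set.seed(seed)
  noise <- if (noiseSd > 0)
    rnorm(length(clean), 0, noiseSd) else numeric(length(clean))
  initialize(protocol, heats = clean + noise)
}

#' Fit the single-site binding model to a titration
#'
#' Levenberg-Marquardt least squares over (N, Ka, dH, baseline), with Ka
#' and N fitted on the log scale for positivity. Starting values come
#' from the curve geometry (molar ratio at half-amplitude for N, the
#' first-injection heat for dH, the late-injection mean for the
#' baseline) combined with a small grid over Ka plus seeded jittered
#' restarts; the lowest residual norm wins. A no-binding verdict ("NB")
#' is returned when the fitted curve explains no more variance than a
#' flat baseline (partial F-test) - mirroring how flat thermograms are
#' reported in binding panels.
#'
#' @param experiment an \linkS4class{ITCExperiment} with heats.
#' @param init optional \linkS4class{ITCModelParams} starting point.
#' @param discardFirst drop the first injection before fitting (common
#'   practice for syringe-diffusion artefacts; default FALSE).
#' @param restarts number of jittered restarts (default 5).
#' @param seed RNG seed for the jitter (default 1).
#' @return an \linkS4class{ITCFit}.
#' @export
fitSingleSite <- function(experiment, init = NULL, discardFirst = FALSE,
                          restarts = 5L, seed = 1L) {
  y <- injectionHeats(experiment)
  .stopIfNot(length(y) > 0L, "experiment has no heats")
  protocol <- experiment
  # the first injection, if discarded, stays in the dilution bookkeeping
  # (the model is still evaluated over the full protocol); only its
  # residual is dropped from the objective
  use <- if (discardFirst) seq_along(y)[-1] else seq_along(y)
  .stopIfNot(length(use) >= 8L, "need at least 8 usable injections")

  residFn <- function(p)
    (y - .itcHeats(exp(p[1]), exp(p[2]), p[3], p[4], protocol))[use]

  ## geometry-based initial values
  base0 <- mean(utils::tail(y, 3))
  amp <- y[1] - base0
  cm <- .itcCumulative(1, 1e6, -1, protocol)
  Mt <- protocol@cellConc *
    (1 - cumsum(cm$dV) / (2 * cm$V0)) / (1 + cumsum(cm$dV) / (2 * cm$V0))
  Xt <- protocol@syringeConc *
    (cumsum(cm$dV) / cm$V0) / (1 + cumsum(cm$dV) / (2 * cm$V0))
  ratio <- Xt / Mt
  half <- which(abs(y - base0) < abs(amp) / 2)[1]
  N0 <- if (is.na(half)) 1 else max(ratio[half], 0.1)
  dH0 <- amp * 1e-6 / (protocol@syringeConc * cm$dV[1])
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -1000

  starts <- list()
  if (!is.null(init))
    starts <- list(c(log(init@N), log(init@Ka), init@dH, init@baseline))
  for (ka0 in c(1e5, 1e6, 1e7, 1e8))
    starts <- c(starts, list(c(log(N0), log(ka0), dH0, base0)))
  set.seed(seed)
  for (k in seq_len(restarts)) {
    b <- starts[[sample.int(length(starts), 1)]]
    starts <- c(starts, list(b + rnorm(4, 0, c(0.2, 0.5,
                                               abs(dH0) * 0.1 + 1, 0.1))))
  }

  best <- NULL
  for (p0 in starts) {
    f <- tryCatch(
      minpack.lm::nls.lm(p0, fn = residFn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200)),
      error = function(e) NULL)
    if (is.null(f) || !all(is.finite(f$par))) next
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  if (is.null(best))
    return(new("ITCFit", params = new("ITCModelParams", N = 1, Ka = 1,
                                      dH = 0, baseline = 0),
               kdNano = NA_real_, se = c(N = NA, Ka = NA, dH = NA,
                                         baseline = NA),
               residualNorm = NA_real_, converged = FALSE,
               noBinding = FALSE,
               message = "optimizer failed from every start"))

  p <- best$par
  params <- new("ITCModelParams", N = exp(p[1]), Ka = exp(p[2]),
                dH = p[3], baseline = p[4])
  nObs <- length(use)
  rssFull <- best$deviance
  rssFlat <- sum((y[use] - mean(y[use]))^2)
  ## partial F-test of the binding signal against a flat baseline
  fStat <- ((rssFlat - rssFull) / 3) / (rssFull / max(nObs - 4, 1))
  pFlat <- stats::pf(fStat, 3, max(nObs - 4, 1), lower.tail = FALSE)
  noBinding <- !is.finite(fStat) || pFlat > 0.01

  se <- .itcSE(best, params, nObs)
  converged <- best$info %in% 1:4

  new("ITCFit", params = params, kdNano = 1e9 / params@Ka,
      se = se, residualNorm = rssFull,
      converged = converged, noBinding = noBinding,
      message = best$message)
}

# delta-method standard errors from the LM hessian (log-scale N, Ka)
.itcSE <- function(fit, params, nObs) {
  out <- c(N = NA_real_, Ka = NA_real_, dH = NA_real_,
           baseline = NA_real_)
  sigma2 <- fit$deviance / max(nObs - 4, 1)
  V <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  if (is.null(V)) return(out)
  sdp <- sqrt(pmax(diag(V), 0))
  out["N"] <- params@N * sdp[1]
  out["Ka"] <- params@Ka * sdp[2]
  out["dH"] <- sdp[3]
  out["baseline"] <- sdp[4]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate replicate fits into mean Kd +/- SD
#'
#' @param fits list of \linkS4class{ITCFit} objects.
#' @return list with meanKd (nM), sdKd (nM), n (converged binding fits
#'   used).
#' @export
aggregateReplicates <- function(fits) {
  ok <- vapply(fits, function(f) isConverged(f) && !isNoBinding(f),
               logical(1))
  .stopIfNot(sum(ok) >= 2L,
             "need at least 2 converged binding fits to aggregate")
  kd <- vapply(fits[ok], kdNano, numeric(1))
  list(meanKd = mean(kd), sdKd = stats::sd(kd), n = sum(ok))
}

#' Read a thermogram CSV
#'
#' Expects columns \code{injection_index}, \code{volume_ul},
#' \code{heat_ucal}.
#'
#' @param path CSV path.
#' @param cellVolume,cellConc,syringeConc,temperature protocol fields.
#' @return an \linkS4class{ITCExperiment}.
#' @export
readThermogram <- function(path, cellVolume = 204.4, cellConc = 20e-6,
                           syringeConc = 200e-6, temperature = 25) {
  d <- utils::read.csv(path)
  req <- c("injection_index", "volume_ul", "heat_ucal")
  .stopIfNot(all(req %in% names(d)),
             paste("thermogram CSV needs columns:",
                   paste(req, collapse = ", ")))
  d <- d[order(d$injection_index), ]
  itcProtocol(cellVolume = cellVolume, cellConc = cellConc,
              syringeConc = syringeConc,
              injectionVolumes = d$volume_ul,
              temperature = temperature, heats = d$heat_ucal)
}
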