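#' Fitted CLIMEX-style parameters for maize
#'
#' The 16 parameters of the maize model: trapezoidal temperature thresholds
#' DV0 < DV1 <= DV2 < DV3 (degrees C), trapezoidal soil-moisture thresholds
#' SM0 < SM1 <= SM2 < SM3 (fractions of holding capacity), and the four
#' stress threshold/rate pairs — cold (TTCS degrees C, THCS per week), heat
#' (TTHS, THHS), dry (SMDS fraction, HDS per week) and wet (SMWS, HWS).
#' Rate signs follow the fitted values (cold and dry rates are negative);
#' only the magnitude enters the accumulation.
#'
#' Defaults are the fitted maize values: DV0 = 10, DV1 = 18, DV2 = 30,
#' DV3 = 35 degrees C; SM0 = 0.1, SM1 = 0.7, SM2 = 0.9, SM3 = 1.3;
#' TTCS = 7, THCS = -0.00007; TTHS = 40, THHS = 0.01; SMDS = 0.1,
#' HDS = -0.009; SMWS = 1.3, HWS = 0.001.
#'
#' @param dv0,dv1,dv2,dv3 Temperature thresholds (degrees C).
#' @param sm0,sm1,sm2,sm3 Soil-moisture thresholds (fractions).
#' @param ttcs,thcs Cold-stress threshold (degrees C) and weekly rate.
#' @param tths,thhs Heat-stress threshold (degrees C) and weekly rate.
#' @param smds,hds Dry-stress threshold (fraction) and weekly rate.
#' @param smws,hws Wet-stress threshold (fraction) and weekly rate.
#' @return List of class `maize_parameters`.
#' @export
maize_parameters <- function(dv0 = 10, dv1 = 18, dv2 = 30, dv3 = 35,
                             sm0 = 0.1, sm1 = 0.7, sm2 = 0.9, sm3 = 1.3,
                             ttcs = 7, thcs = -0.00007,
                             tths = 40, thhs = 0.01,
                             smds = 0.1, hds = -0.009,
                             smws = 1.3, hws = 0.001) {
  p <- list(dv0 = dv0, dv1 = dv1, dv2 = dv2, dv3 = dv3,
            sm0 = sm0, sm1 = sm1, sm2 = sm2, sm3 = sm3,
            ttcs = ttcs, thcs = thcs, tths = tths, thhs = thhs,
            smds = smds, hds = hds, smws = smws, hws = hws)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), logical(1))))
    stop("all parameters must be finite scalars")
  if (!(p$dv0 < p$dv1 && p$dv1 <= p$dv2 && p$dv2 < p$dv3))
    stop("temperature thresholds must satisfy dv0 < dv1 <= dv2 < dv3")
  if (!(p$sm0 < p$sm1 && p$sm1 <= p$sm2 && p$sm2 < p$sm3))
    stop("moisture thresholds must satisfy sm0 < sm1 <= sm2 < sm3")
  structure(p, class = "maize_parameters")
}

#' @export
print.maize_parameters <- function(x, ...) {
  cat("<maize_parameters>\n")
  cat(sprintf("  temperature DV0-DV3: %g %g %g %g degC\n",
              x$dv0, x$dv1, x$dv2, x$dv3))
  cat(sprintf("  moisture   SM0-SM3: %g %g %g %g\n",
              x$sm0, x$sm1, x$sm2, x$sm3))
  cat(sprintf("  cold TTCS %g THCS %g | heat TTHS %g THHS %g\n",
              x$ttcs, x$thcs, x$tths, x$thhs))
  cat(sprintf("  dry  SMDS %g HDS %g  | wet  SMWS %g HWS %g\n",
              x$smds, x$hds, x$smws, x$hws))
  invisible(x)
}

#' Read parameters from a config file
#'
#' JSON object keyed by the upper- or lower-case acronyms (DV0..DV3,
#' SM0..SM3, TTCS, THCS, TTHS, THHS, SMDS, HDS, SMWS, HWS); absent keys
#' keep their fitted defaults.
#'
#' @param path JSON file.
#' @return A [maize_parameters].
#' @export
read_parameters <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  names(raw) <- tolower(names(raw))
  known <- names(formals(maize_parameters))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    stop(sprintf("unknown parameter key(s): %s", paste(extra, collapse = ", ")))
  do.call(maize_parameters, raw)
}

#' Perturb a single parameter
#'
#' Copy-with-change for the one-at-a-time sensitivity analysis. Threshold
#' parameters are shifted additively; rates are scaled in magnitude
#' (`mode = "relative"`, `delta` a fractional change, sign preserved).
#' The perturbed set must still satisfy the ordering invariants.
#'
#' @param p A [maize_parameters].
#' @param name Parameter id (e.g. `"dv0"`, `"thcs"`; case-insensitive).
#' @param delta Signed step: degrees C / fraction for `"absolute"`,
#'   fractional change for `"relative"`.
#' @param mode `"absolute"` or `"relative"`.
#' @return A new [maize_parameters]; ordering violations are an error.
#' @export
perturb_parameter <- function(p, name, delta,
                              mode = c("absolute", "relative")) {
  stopifnot(inherits(p, "maize_parameters"))
  mode <- match.arg(mode)
  name <- tolower(name)
  if (!name %in% names(p)) stop(sprintf("unknown parameter '%s'", name))
  q <- unclass(p)
  q[[name]] <- if (mode == "absolute") q[[name]] + delta
               else q[[name]] * (1 + delta)
  out <- try(do.call(maize_parameters, q), silent = TRUE)
  if (inherits(out, "try-error"))
    stop(sprintf("perturbing '%s' by %g violates parameter ordering: %s",
                 name, delta, attr(out, "condition")$message))
  out
}
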