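# Parameter presets for the two model classes, read from the packaged JSON
# (inst/extdata/neuron_params.json). Values follow the published parameter
# tables; variants excluded there (duplicate parameter sets, non-standard
# equations, or instability at the 0.1 ms grid) are kept in the file but
# flagged, and are not returned by the *_variants() helpers.

the <- new.env(parent = emptyenv())

param_db <- function() {
  if (is.null(the$db)) {
    path <- system.file("extdata", "neuron_params.json", package = "lnspike",
                        mustWork = TRUE)
    the$db <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  the$db
}

#' Izhikevich model parameters for one variant
#'
#' Variants are labelled A-T after the firing patterns of the current-injection
#' repertoire; six of them (G, I, L, O, R, T) are excluded from the study set
#' because of repeated parameter sets, non-standard equations or grid
#' instability, but their parameters can still be requested with
#' `include_excluded = TRUE`.
#'
#' @param label variant letter, e.g. `"A"`.
#' @param include_excluded allow access to excluded variants.
#' @return object of class `izhikevich_params` with fields `a`, `b`, `c`, `d`
#'   (unitless model constants), `xi` (weight factor: smallest voltage jump
#'   that triggers a spike from rest), `i_ext` (constant external current),
#'   `v_th` (spike-cut value, mV), `label` and `name`.
#' @export
izhikevich_params <- function(label, include_excluded = FALSE) {
  db <- param_db()$izhikevich
  row <- db$variants[db$variants$label == label, ]
  if (nrow(row) != 1L) stopf("unknown Izhikevich variant '%s'", label)
  if (!row$included && !include_excluded)
    stopf("Izhikevich variant '%s' is excluded from the study set", label)
  structure(list(a = row$a, b = row$b, c = row$c, d = row$d, xi = row$xi,
                 i_ext = row$i_ext, v_th = db$common$v_th,
                 label = row$label, name = row$name),
            class = "izhikevich_params")
}

#' AMAT model parameters for one variant
#'
#' All variants share the common membrane, synaptic and refractory parameters
#' (footer of the published table); variants differ only in the threshold
#' jump amplitudes `alpha1`, `alpha2` (mV) and the voltage-coupling gain
#' `beta`. Variants L and R duplicate A and O and are excluded.
#'
#' @inheritParams izhikevich_params
#' @return object of class `amat_params`.
#' @export
amat_params <- function(label, include_excluded = FALSE) {
  db <- param_db()$amat
  row <- db$variants[db$variants$label == label, ]
  if (nrow(row) != 1L) stopf("unknown AMAT variant '%s'", label)
  if (!row$included && !include_excluded)
    stopf("AMAT variant '%s' is excluded from the study set", label)
  cm <- db$common
  structure(list(alpha1 = row$alpha1, alpha2 = row$alpha2, beta = row$beta,
                 e_l = cm$e_l, omega = cm$omega, c_m = cm$c_m,
                 tau_m = cm$tau_m, tau_1 = cm$tau_1, tau_2 = cm$tau_2,
                 tau_v = cm$tau_v, tau_ref = cm$tau_ref,
                 tau_syn_e = cm$tau_syn_e, tau_syn_i = cm$tau_syn_i,
                 label = row$label, name = row$name),
            class = "amat_params")
}

#' Included variant labels for a model class
#' @param class `"izhikevich"` or `"amat"`.
#' @return character vector of variant letters in the study set (14 for the
#'   Izhikevich class, 18 for the AMAT class).
#' @export
model_variants <- function(class = c("izhikevich", "amat")) {
  class <- match.arg(class)
  v <- param_db()[[class]]$variants
  v$label[v$included]
}

#' @export
print.izhikevich_params <- function(x, ...) {
  cat(sprintf("<izhikevich_params> %s (%s): a=%g b=%g c=%g d=%g xi=%g I_ext=%g\n",
              x$label, x$name, x$a, x$b, x$c, x$d, x$xi, x$i_ext))
  invisible(x)
}

#' @export
print.amat_params <- function(x, ...) {
  cat(sprintf("<amat_params> %s (%s): alpha1=%g alpha2=%g beta=%g\n",
              x$label, x$name, x$alpha1, x$alpha2, x$beta))
  invisible(x)
}

#' Model specification (class + variant)
#'
#' Small handle combining a model class and a variant label, used by the
#' sweep-level functions (activation functions, transfer functions, stepped
#' tests).
#'
#' @param class `"izhikevich"` or `"amat"`.
#' @param label variant letter.
#' @return object of class `model_spec` with the resolved parameter set.
#' @export
model_spec <- function(class = c("izhikevich", "amat"), label = "A") {
  class <- match.arg(class)
  params <- switch(class,
                   izhikevich = izhikevich_params(label),
                   amat = amat_params(label))
  structure(list(class = class, label = label, params = params),
            class = "model_spec")
}

#' Background-noise presets
#'
#' The three background-current regimes used throughout: no noise, balanced
#' noise (`mu = 0`) and biased (net inhibitory) noise. Means and standard
#' deviations are class-specific: unitless currents for the Izhikevich class
#' (`sigma` = 0.1 / 0.2), picoamperes for the AMAT class (`sigma` = 100 /
#' 200 pA). For the AMAT class the noise is delivered as excitatory and
#' inhibitory background Poisson spike trains with fixed weights
#' `w_E,bg = 1 pA`, `w_I,bg = -4/3 pA`; the preset carries the event rates
#' `nu_E`, `nu_I` obtained by [solve_background_rates()].
#'
#' @param name `"none"`, `"balanced"` or `"biased"`.
#' @param class model class the preset is for.
#' @return object of class `noise_preset` with fields `name`, `class`, `mu`,
#'   `sigma`, and for the AMAT class `nu_e`, `nu_i`, `w_e_bg`, `w_i_bg`.
#' @export
noise_preset <- function(name = c("none", "balanced", "biased"),
                         class = c("izhikevich", "amat")) {
  name <- match.arg(name)
  class <- match.arg(class)
  ms <- switch(name,
               none = c(0, 0),
               balanced = if (class == "izhikevich") c(0, 0.1) else c(0, 100),
               biased = if (class == "izhikevich") c(-0.1, 0.2) else c(-100, 200))
  out <- list(name = name, class = class, mu = ms[1], sigma = ms[2])
  if (class == "amat") {
    if (name == "none") {
      out$nu_e <- 0
      out$nu_i <- 0
    } else {
      r <- solve_background_rates(ms[1], ms[2])
      out$nu_e <- r[["nu_e"]]
      out$nu_i <- r[["nu_i"]]
    }
    out$w_e_bg <- 1
    out$w_i_bg <- -4 / 3
  }
  structure(out, class = "noise_preset")
}

#' @export
print.noise_preset <- function(x, ...) {
  cat(sprintf("<noise_preset> %s (%s): mu=%g sigma=%g\n",
              x$name, x$class, x$mu, x$sigma))
  invisible(x)
}
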