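#' Conductance-based LIF neuron parameters
#'
#' Parameters of the leaky integrate-and-fire membrane with exponentially
#' decaying AMPA and GABA conductances:
#' `Cm dV/dt = gA (E_ampa - V) + gG (E_gaba - V) + g_rest (E_rest - V)`.
#'
#' The default constants for the two simulated populations are calibrated
#' against the model's functional constraints: a granule cell needs at least
#' three near-coincident mossy-fiber EPSPs (1 nS peak each) to spike, while
#' one or two are insufficient, and the resulting population response
#' probabilities under sensory-like stimulation match the calibrated regime
#' (see the methods vignette).
#'
#' @param Cm Membrane capacitance (pF).
#' @param g_rest Leak conductance (nS).
#' @param E_rest,E_ampa,E_gaba Resting and synaptic reversal potentials (mV).
#' @param V_th Spike threshold (mV).
#' @param V_reset Post-spike reset potential (mV).
#' @param t_ref Absolute refractory period (ms).
#' @param tau_ampa,tau_gaba Conductance decay time constants (ms).
#' @return An object of class `grc_neuron_params`.
#' @export
neuron_params <- function(Cm, g_rest, E_rest, E_ampa = 0, E_gaba = -80,
                          V_th, V_reset, t_ref, tau_ampa, tau_gaba) {
  stopifnot(Cm > 0, g_rest > 0, tau_ampa > 0, tau_gaba > 0, t_ref >= 0)
  if (!(E_gaba <= E_rest && E_rest < V_th && V_th <= E_ampa))
    stop("require E_gaba <= E_rest < V_th <= E_ampa")
  structure(list(Cm = Cm, g_rest = g_rest, E_rest = E_rest, E_ampa = E_ampa,
                 E_gaba = E_gaba, V_th = V_th, V_reset = V_reset,
                 t_ref = t_ref, tau_ampa = tau_ampa, tau_gaba = tau_gaba),
            class = "grc_neuron_params")
}

#' Default neuron parameters per population
#'
#' @return Named list with `grc` and `goc` [neuron_params()].
#' @export
default_neuron_params <- function() {
  list(
    grc = neuron_params(Cm = 3, g_rest = 0.3, E_rest = -70, V_th = -48.5,
                        V_reset = -70, t_ref = 1, tau_ampa = 0.5,
                        tau_gaba = 10),
    goc = neuron_params(Cm = 28, g_rest = 3.0, E_rest = -65, V_th = -54,
                        V_reset = -67, t_ref = 2, tau_ampa = 1.5,
                        tau_gaba = 10)
  )
}

#' Synaptic weight configuration
#'
#' The four peak conductances of the circuit. `w_mf_grc_total` is the total
#' mossy fiber to granule cell AMPA conductance (4.0 nS), split evenly over
#' the granule cell dendrites (1.0 nS each with 4 dendrites). The GoC->GrC
#' GABA peak is fixed at 0.5 nS; the effective inhibition level is controlled
#' indirectly through the feedforward (`w_mf_goc`) and feedback (`w_grc_goc`)
#' excitatory drives onto Golgi cells. Setting both to zero silences Golgi
#' cells and reproduces the DART condition (blocked synaptic inhibition onto
#' granule cells).
#'
#' @param w_mf_grc_total Total MF->GrC peak AMPA conductance (nS).
#' @param w_goc_grc GoC->GrC peak GABA conductance (nS).
#' @param w_mf_goc MF->GoC peak AMPA conductance, the feedforward knob (nS).
#' @param w_grc_goc GrC->GoC peak AMPA conductance, the feedback knob (nS).
#' @param label Name of the configuration.
#' @return An object of class `grc_weights`.
#' @export
weight_config <- function(w_mf_grc_total = 4.0, w_goc_grc = 0.5,
                          w_mf_goc = 0.1, w_grc_goc = 0.015,
                          label = "control") {
  w <- c(w_mf_grc_total, w_goc_grc, w_mf_goc, w_grc_goc)
  if (any(w < 0)) stop("synaptic weights must be >= 0")
  structure(list(w_mf_grc_total = w_mf_grc_total, w_goc_grc = w_goc_grc,
                 w_mf_goc = w_mf_goc, w_grc_goc = w_grc_goc, label = label),
            class = "grc_weights")
}

#' Named weight configurations of the inhibition sweep
#'
#' The seven (feedforward, feedback) drive combinations used to dissect the
#' inhibitory loops, from fully blocked inhibition (DART) to strong combined
#' drive, plus the default control configuration.
#'
#' @param label Optional configuration name; with `NULL` the full named list
#'   is returned.
#' @return A `grc_weights` object, or a named list of them.
#' @export
weight_presets <- function(label = NULL) {
  tab <- list(
    "control"       = c(0.1, 0.015),
    "DART"          = c(0.0, 0.0),
    "Feedforward+"  = c(0.2, 0.0),
    "Feedback+"     = c(0.0, 0.03),
    "Combined+"     = c(0.1, 0.015),
    "Feedforward++" = c(0.3, 0.0),
    "Feedback++"    = c(0.0, 0.06),
    "Combined++"    = c(0.2, 0.015),
    "Inh+"          = c(0.1, 0.005),
    "Inh++"         = c(0.1, 0.015)
  )
  make <- function(nm) weight_config(w_mf_goc = tab[[nm]][1],
                                     w_grc_goc = tab[[nm]][2], label = nm)
  if (is.null(label)) {
    out <- lapply(names(tab), make)
    names(out) <- names(tab)
    return(out)
  }
  if (!label %in% names(tab)) stop("unknown weight preset: ", label)
  make(label)
}

#' Is a weight configuration the DART (no-inhibition) condition?
#' @param weights A `grc_weights`.
#' @return Logical.
#' @export
is_dart <- function(weights) {
  weights$w_mf_goc == 0 && weights$w_grc_goc == 0
}
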