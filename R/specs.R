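# Parameter objects for the synthetic S1S2 protocol generator. Defaults
# reproduce the reference synthetic study conditions: S1 BCL 600 ms, S2
# coupling intervals 500:-50:350 then 340:-10:180 ms (21 trains), 1.2 s
# between trains, ERP 200 ms, a 10-electrode circular catheter of 10 mm
# radius (9 neighboring bipoles) plus 4 CS bipoles at 35-50 mm, stimulus
# artifacts of 4.7 mV / 8 ms and atrial activities of 2 mV / 35 ms with
# exponential restitution decay starting from 2 mV and 650 mm/s.

#' S1S2 protocol specification
#'
#' @param s1_bcl S1 basic cycle length in ms.
#' @param n_s1_per_train number of S1 stimuli per pacing train.
#' @param s2_intervals strictly decreasing S2 coupling intervals in ms, one
#'   per train.
#' @param inter_train_gap time from the S2 stimulus to the first S1 of the
#'   next train in ms; must exceed `s1_bcl` (pipeline assumption).
#' @param erp effective refractory period in ms: S2 stimuli with coupling
#'   interval below `erp` do not capture.
#' @return a `ProtocolSpec` list.
#' @export
protocolSpec <- function(s1_bcl = 600, n_s1_per_train = 4,
                         s2_intervals = c(seq(500, 350, -50),
                                          seq(340, 180, -10)),
                         inter_train_gap = 1200, erp = 200) {
  .stop_if_not(all(diff(s2_intervals) < 0),
               "s2_intervals must be strictly decreasing")
  .stop_if_not(inter_train_gap > s1_bcl,
               "inter_train_gap must exceed s1_bcl (pipeline assumption)")
  structure(list(s1_bcl = s1_bcl, n_s1_per_train = n_s1_per_train,
                 s2_intervals = s2_intervals,
                 inter_train_gap = inter_train_gap, erp = erp),
            class = "ProtocolSpec")
}

#' Catheter layout for the synthetic setup
#'
#' A planar circular mapping catheter with equidistant electrodes forming
#' adjacent-pair bipoles, plus coronary-sinus (CS) bipoles placed along the
#' `cs_angle_deg` direction at the given distances from the stimulating
#' bipole.
#'
#' @param circular_radius circle radius in mm.
#' @param n_electrodes electrodes on the circle (bipoles:
#'   `n_electrodes - 1`).
#' @param cs_bipole_distances CS bipole distances to the stimulating bipole
#'   (mm).
#' @param stim_channel index of the stimulating circular bipole.
#' @param cs_angle_deg direction (degrees, in the catheter plane) from the
#'   stimulating bipole along which CS bipoles are placed; the default lies
#'   on the default fiber axis so CS activation times are isotropic.
#' @param cs_electrode_spacing electrode spacing within a CS bipole (mm).
#' @return a `CatheterLayout` list.
#' @export
catheterLayout <- function(circular_radius = 10, n_electrodes = 10,
                           cs_bipole_distances = c(35, 40, 45, 50),
                           stim_channel = 1, cs_angle_deg = 162,
                           cs_electrode_spacing = 2) {
  .stop_if_not(n_electrodes >= 3, "need at least 3 electrodes")
  structure(list(circular_radius = circular_radius,
                 n_electrodes = n_electrodes,
                 cs_bipole_distances = cs_bipole_distances,
                 stim_channel = stim_channel, cs_angle_deg = cs_angle_deg,
                 cs_electrode_spacing = cs_electrode_spacing),
            class = "CatheterLayout")
}

#' Stimulus and atrial waveform parameters
#'
#' @param stim_amplitude stimulation artifact peak-to-peak amplitude (mV).
#' @param stim_duration total artifact duration (ms).
#' @param stim_phase1 duration of the first (positive) phase (ms).
#' @param atrial_amplitude atrial activity peak-to-peak amplitude (mV).
#' @param atrial_duration atrial activity duration (ms).
#' @param atrial_lat_frac position of the steepest downstroke (the LAT
#'   reference point) within the atrial waveform, as a fraction of its
#'   duration; clinical bipolar activities are typically asymmetric with a
#'   longer leading lobe.
#' @return a `WaveformSpec` list.
#' @export
waveformSpec <- function(stim_amplitude = 4.7, stim_duration = 8,
                         stim_phase1 = 2, atrial_amplitude = 2,
                         atrial_duration = 35, atrial_lat_frac = 0.6) {
  .stop_if_not(all(c(stim_duration, stim_phase1, atrial_duration) > 0) &&
               stim_amplitude >= 0 && atrial_amplitude >= 0,
               "durations must be positive, amplitudes non-negative")
  .stop_if_not(stim_phase1 < stim_duration,
               "stim_phase1 must be shorter than stim_duration")
  structure(list(stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration, stim_phase1 = stim_phase1,
                 atrial_amplitude = atrial_amplitude,
                 atrial_duration = atrial_duration,
                 atrial_lat_frac = atrial_lat_frac),
            class = "WaveformSpec")
}

#' Restitution model for the synthetic tissue response
#'
#' Amplitude and conduction velocity follow saturating exponential
#' restitution curves
#' `q(s2) = q0 * (1 - a * exp(-(s2 - erp) / tau))`,
#' monotone non-decreasing in the S2 coupling interval and asymptoting to
#' the baseline `q0` for long intervals. S1 responses use the baselines.
#' Activation times assume elliptic anisotropic conduction: the distance
#' component transverse to the fiber axis is stretched by the anisotropy
#' factor.
#'
#' @param cv0 baseline (longitudinal) conduction velocity in mm/s.
#' @param amp0 baseline atrial amplitude in mV.
#' @param anisotropy ratio of longitudinal to transverse velocity.
#' @param fiber_angle_deg fiber (ellipse long-axis) direction in the
#'   catheter plane, degrees.
#' @param amp_decay_a,amp_tau amplitude restitution depth (fraction) and
#'   time constant (ms).
#' @param cv_decay_a,cv_tau velocity restitution depth and time constant.
#' @return a `RestitutionModel` list.
#' @export
restitutionModel <- function(cv0 = 650, amp0 = 2, anisotropy = 1.5,
                             fiber_angle_deg = 162, amp_decay_a = 0.5,
                             amp_tau = 60, cv_decay_a = 0.5, cv_tau = 60) {
  .stop_if_not(cv0 > 0 && amp0 >= 0 && anisotropy >= 1,
               "cv0 > 0, amp0 >= 0 and anisotropy >= 1 required")
  .stop_if_not(amp_decay_a < 1 && cv_decay_a < 1,
               "decay depths must stay below 1")
  structure(list(cv0 = cv0, amp0 = amp0, anisotropy = anisotropy,
                 fiber_angle_deg = fiber_angle_deg,
                 amp_decay_a = amp_decay_a, amp_tau = amp_tau,
                 cv_decay_a = cv_decay_a, cv_tau = cv_tau),
            class = "RestitutionModel")
}

#' Restitution curves of the synthetic model
#'
#' @param model a [restitutionModel()].
#' @param s2 S2 coupling interval(s) in ms; `Inf` gives the baseline.
#' @param erp effective refractory period in ms (curves are anchored at the
#'   ERP, where the response has decayed by the configured depth).
#' @return amplitude in mV / velocity in mm/s.
#' @export
ampAt <- function(model, s2, erp) {
  model$amp0 * (1 - model$amp_decay_a * exp(-pmax(s2 - erp, 0) /
                                            model$amp_tau))
}

#' @rdname ampAt
#' @export
cvAt <- function(model, s2, erp) {
  model$cv0 * (1 - model$cv_decay_a * exp(-pmax(s2 - erp, 0) / model$cv_tau))
}

#' Bipole geometry of a catheter layout
#'
#' Electrode `i` sits at angle `2*pi*(i-1)/n` on the circle; circular bipole
#' `j` is the adjacent pair `(j, j+1)` and its position the electrode-pair
#' mean. CS bipoles lie along `cs_angle_deg` at the configured distances.
#'
#' @param layout a [catheterLayout()].
#' @return list with `centers` (bipoles x 3, mm), `electrodes` (list of
#'   2 x 3 matrices), `catheter` labels, `names`, and `stim` index.
#' @export
bipoleGeometry <- function(layout) {
  ne <- layout$n_electrodes
  ang <- 2 * pi * (seq_len(ne) - 1) / ne
  el <- cbind(layout$circular_radius * cos(ang),
              layout$circular_radius * sin(ang), 0)
  nb <- ne - 1L
  electrodes <- lapply(seq_len(nb), function(j) el[c(j, j + 1L), ,
                                                   drop = FALSE])
  centers <- t(vapply(electrodes, colMeans, numeric(3)))
  names <- paste0("PV", seq_len(nb))
  catheter <- rep("PV", nb)
  stim <- layout$stim_channel
  if (length(layout$cs_bipole_distances)) {
    u <- c(cos(layout$cs_angle_deg * pi / 180),
           sin(layout$cs_angle_deg * pi / 180), 0)
    half <- layout$cs_electrode_spacing / 2
    for (k in seq_along(layout$cs_bipole_distances)) {
      ctr <- centers[stim, ] + layout$cs_bipole_distances[k] * u
      electrodes <- c(electrodes,
                      list(rbind(ctr - half * u, ctr + half * u)))
      centers <- rbind(centers, ctr)
      names <- c(names, paste0("CS", k))
      catheter <- c(catheter, "CS")
    }
  }
  rownames(centers) <- names
  list(centers = centers, electrodes = electrodes, catheter = catheter,
       names = names, stim = stim)
}
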