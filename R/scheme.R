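#' Kinetic scheme for KF binding and the nucleotide-addition cycle
#'
#' Collects the rate constants governing a simulated single-molecule
#' polymerisation experiment. Binding of KF to the immobilised DNA is
#' pseudo-first-order (enzyme concentration folded into `binding_rate`).
#' Before nucleotide addition the bound (binary) complex interconverts
#' between fingers-open and fingers-closed at `k_close`/`k_open` and
#' dissociates at `unbinding_rate_pre` (default gives a mean bound time of
#' ~10 s). After nucleotide addition each bound episode runs the
#' nucleotide-addition cycle: a fingers-open wait for dNTP binding
#' (`dntp_wait_rate`, proportional to dNTP concentration), then a
#' fingers-closed dwell whose exit rate is the incorporation rate of the
#' incoming nucleotide, repeated until `n_max` bases are added, after which
#' the complex reverts to binary-complex dynamics but dissociates at the
#' faster `unbinding_rate_post` (blunt/short-overhang DNA binds KF weakly).
#'
#' Default conformational rates are those measured for the binary complex on
#' extensible DNA (k_close = 1.4 s^-1, k_open = 5.3 s^-1); per-nucleotide
#' incorporation rates default to the single-nucleotide measurements
#' (dTTP 3.4, dATP 2, dCTP 1, dGTP 1.5 s^-1). `binding_rate` and
#' `unbinding_rate_post` are not reported in the source measurements and
#' their defaults are qualitative (several binding events per minute;
#' prompt dissociation after full extension).
#'
#' @param binding_rate per-second pseudo-first-order KF binding rate.
#' @param unbinding_rate_pre per-second dissociation rate of the binary
#'   complex (default 0.1, mean bound time ~10 s).
#' @param unbinding_rate_post per-second dissociation rate after full
#'   extension.
#' @param k_close,k_open per-second fingers closing/opening rates of the
#'   binary complex.
#' @param dntp_wait_rate per-second rate of leaving the fingers-open state
#'   during polymerisation (dNTP binding; proportional to concentration).
#' @param incorporation_rates named numeric vector of per-second
#'   fingers-closed exit rates keyed by the *incorporated* nucleotide
#'   (names "A", "C", "G", "T").
#' @param n_max maximum number of incorporations the template permits
#'   (0, 1, 5, 10 or 15 in the canonical experiments).
#' @param template_sequence templating bases 5'->3'; base i pairs with the
#'   complementary dNTP, whose entry in `incorporation_rates` sets the
#'   closed-dwell exit rate of incorporation i.
#' @param t_add time (s) at which nucleotides are added; `Inf` means never
#'   (binary-complex-only experiment), 0 means present from the start.
#' @param overhang_cutoff after extension stops, dissociation uses
#'   `unbinding_rate_post` only if the remaining single-stranded template
#'   overhang (`nchar(template_sequence) - n_max`) is at most this many
#'   bases (blunt or short-overhang DNA binds KF weakly); longer leftover
#'   overhangs retain KF at `unbinding_rate_pre`.
#' @return An object of class `kinetic_scheme`.
#' @export
#' @examples
#' sch <- kinetic_scheme(n_max = 5, t_add = 72)
#' sch
kinetic_scheme <- function(binding_rate = 0.05,
                           unbinding_rate_pre = 0.1,
                           unbinding_rate_post = 1.0,
                           k_close = 1.4,
                           k_open = 5.3,
                           dntp_wait_rate = 50,
                           incorporation_rates = c(A = 2, C = 1, G = 1.5, T = 3.4),
                           n_max = 15,
                           template_sequence = "ATAATCACTAGCGAG",
                           t_add = 72,
                           overhang_cutoff = 4) {
  rates <- c(binding_rate = binding_rate,
             unbinding_rate_pre = unbinding_rate_pre,
             unbinding_rate_post = unbinding_rate_post,
             k_close = k_close, k_open = k_open,
             dntp_wait_rate = dntp_wait_rate,
             incorporation_rates)
  if (!all(is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0")
  if (!all(c("A", "C", "G", "T") %in% names(incorporation_rates)))
    stop("incorporation_rates must be named with bases A, C, G, T")
  if (!is.character(template_sequence) || length(template_sequence) != 1L)
    stop("template_sequence must be a single string")
  tmpl <- strsplit(toupper(template_sequence), "")[[1]]
  if (length(tmpl) && !all(tmpl %in% c("A", "C", "G", "T")))
    stop("template_sequence may only contain A, C, G, T")
  if (n_max < 0 || n_max != round(n_max)) stop("n_max must be a count")
  if (n_max > length(tmpl))
    stop("n_max (", n_max, ") exceeds template length (", length(tmpl), ")")
  if (is.na(t_add) || t_add < 0) stop("t_add must be >= 0 (Inf allowed)")
  structure(list(
    binding_rate = binding_rate,
    unbinding_rate_pre = unbinding_rate_pre,
    unbinding_rate_post = unbinding_rate_post,
    k_close = k_close,
    k_open = k_open,
    dntp_wait_rate = dntp_wait_rate,
    incorporation_rates = incorporation_rates[c("A", "C", "G", "T")],
    n_max = as.integer(n_max),
    template_sequence = paste(tmpl, collapse = ""),
    t_add = t_add,
    overhang_cutoff = overhang_cutoff
  ), class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme (per-second rates)\n")
  cat(sprintf("  binding %.3g | unbind pre %.3g / post %.3g\n",
              x$binding_rate, x$unbinding_rate_pre, x$unbinding_rate_post))
  cat(sprintf("  binary complex: k_close %.3g, k_open %.3g\n",
              x$k_close, x$k_open))
  cat(sprintf("  dNTP wait %.3g; incorporation A=%.3g C=%.3g G=%.3g T=%.3g\n",
              x$dntp_wait_rate, x$incorporation_rates[["A"]],
              x$incorporation_rates[["C"]], x$incorporation_rates[["G"]],
              x$incorporation_rates[["T"]]))
  cat(sprintf("  template %s (n_max %d), t_add %s s\n",
              x$template_sequence, x$n_max, format(x$t_add)))
  invisible(x)
}

# incorporated nucleotide for each templating position (Watson-Crick)
complement_base <- function(b) c(A = "T", T = "A", G = "C", C = "G")[b]

# per-position closed-state exit rates for the first n_max incorporations
incorporation_rate_by_position <- function(scheme) {
  if (scheme$n_max == 0L) return(numeric(0))
  tmpl <- strsplit(scheme$template_sequence, "")[[1]][seq_len(scheme$n_max)]
  unname(scheme$incorporation_rates[complement_base(tmpl)])
}

#' Photophysics and camera model for trace rendering
#'
#' Parameters mapping a ground-truth state path onto donor-excitation
#' donor-emission (DD) and donor-excitation acceptor-emission (DA)
#' camera-frame intensities. A dual-labelled bound KF emits `I_total`
#' counts per frame-time split between channels by the FRET efficiency of
#' its conformational state; a donor-only KF emits at `E_donor_only`.
#' Frames are `frame_dt` seconds (40 ms, 25 Hz). The red localisation
#' laser used to find the DNA spots adds `red_excess_DA` counts to the DA
#' channel during the first `red_laser_window` seconds. Each binding event
#' is a fresh KF molecule drawn from `label_fractions`
#' (dual / donor-only / acceptor-only / unlabelled); acceptor photobleaching
#' converts a dual-labelled complex to donor-only emission mid-event, donor
#' bleaching extinguishes both channels.
#'
#' @param frame_dt camera frame time in seconds (default 0.04).
#' @param I_total mean total emission (AU/frame) of a bound dual-labelled KF.
#' @param E_open,E_closed apparent FRET efficiency of the fingers-open /
#'   fingers-closed states (defaults 0.4 / 0.6).
#' @param E_donor_only apparent FRET efficiency of donor-only KF (leakage).
#' @param background_DD,background_DA constant camera background per channel
#'   (AU/frame).
#' @param noise_sd per-channel Gaussian camera noise SD (AU/frame).
#' @param acceptor_bleach_rate,donor_bleach_rate per-second bleaching rates
#'   while bound.
#' @param red_laser_window seconds of initial red-laser localisation
#'   illumination (default 2.4).
#' @param red_excess_DA extra DA counts per frame during the red window.
#' @param label_fractions probabilities of the four labelling species;
#'   must sum to 1.
#' @return An object of class `photophysics_model`.
#' @export
photophysics_model <- function(frame_dt = 0.04,
                               I_total = 600,
                               E_open = 0.4,
                               E_closed = 0.6,
                               E_donor_only = 0.05,
                               background_DD = 100,
                               background_DA = 100,
                               noise_sd = 40,
                               acceptor_bleach_rate = 0.05,
                               donor_bleach_rate = 0.02,
                               red_laser_window = 2.4,
                               red_excess_DA = 800,
                               label_fractions = c(dual = 0.15,
                                                   donor_only = 0.30,
                                                   acceptor_only = 0.30,
                                                   unlabelled = 0.25)) {
  if (frame_dt <= 0) stop("frame_dt must be > 0")
  Es <- c(E_open, E_closed, E_donor_only)
  if (any(Es < 0 | Es > 1)) stop("FRET efficiencies must lie in [0, 1]")
  need <- c("dual", "donor_only", "acceptor_only", "unlabelled")
  if (!all(need %in% names(label_fractions)))
    stop("label_fractions must be named dual/donor_only/acceptor_only/unlabelled")
  label_fractions <- label_fractions[need]
  if (any(label_fractions < 0) || abs(sum(label_fractions) - 1) > 1e-9)
    stop("label_fractions must be non-negative and sum to 1")
  if (noise_sd < 0 || acceptor_bleach_rate < 0 || donor_bleach_rate < 0)
    stop("noise and bleach rates must be >= 0")
  structure(list(
    frame_dt = frame_dt, I_total = I_total,
    E_open = E_open, E_closed = E_closed, E_donor_only = E_donor_only,
    background_DD = background_DD, background_DA = background_DA,
    noise_sd = noise_sd,
    acceptor_bleach_rate = acceptor_bleach_rate,
    donor_bleach_rate = donor_bleach_rate,
    red_laser_window = red_laser_window, red_excess_DA = red_excess_DA,
    label_fractions = label_fractions
  ), class = "photophysics_model")
}

#' @export
print.photophysics_model <- function(x, ...) {
  cat("Photophysics model\n")
  cat(sprintf("  frame %.0f ms, I_total %.0f AU, E* open/closed %.2f/%.2f\n",
              1000 * x$frame_dt, x$I_total, x$E_open, x$E_closed))
  cat(sprintf("  background DD/DA %.0f/%.0f AU, noise SD %.0f AU\n",
              x$background_DD, x$background_DA, x$noise_sd))
  cat(sprintf("  bleach acceptor/donor %.3g/%.3g s^-1; red window %.1f s (+%.0f AU DA)\n",
              x$acceptor_bleach_rate, x$donor_bleach_rate,
              x$red_laser_window, x$red_excess_DA))
  cat("  label fractions:",
      paste(sprintf("%s %.2f", names(x$label_fractions), x$label_fractions),
            collapse = ", "), "\n")
  invisible(x)
}
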