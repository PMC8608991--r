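#' Build a registered quadripolar DBS lead model
#'
#' Geometry comes from the versioned registry shipped with the package
#' (\code{extdata/leads.yaml}). The Medtronic 3389 has four cylindrical
#' contacts (C0..C3) of 1.5 mm length with 0.5 mm edge gaps, so adjacent
#' contact centres are 2.0 mm apart; the centre of C0 sits 0.75 mm from the
#' lead tip.
#'
#' @param name lead identifier, e.g. \code{"medtronic3389"}.
#' @return an object of class \code{lead_model} with fields \code{name},
#'   \code{n_contacts}, \code{contact_length}, \code{intercontact_gap},
#'   \code{tip_to_first_contact} (all mm).
#' @export
build_lead <- function(name = "medtronic3389") {
  reg <- yaml::read_yaml(system.file("extdata", "leads.yaml",
                                     package = "dbsconn", mustWork = TRUE))
  if (!name %in% names(reg$leads))
    stop(sprintf("unknown lead '%s'; registered: %s", name,
                 paste(names(reg$leads), collapse = ", ")))
  g <- reg$leads[[name]]
  stopifnot(g$n_contacts >= 1, g$contact_length > 0, g$intercontact_gap > 0)
  structure(c(list(name = name), g), class = "lead_model")
}

#' @export
print.lead_model <- function(x, ...) {
  cat(sprintf(
    "<lead_model> %s: %d contacts, %.2f mm length, %.2f mm gap, C0 centre at %.2f mm\n",
    x$name, x$n_contacts, x$contact_length, x$intercontact_gap,
    x$tip_to_first_contact))
  invisible(x)
}

#' Lead placement in world space
#' @param tip world mm coordinate of the lead tip.
#' @param direction 3-vector along the lead shaft (tip towards connector);
#'   normalized internally, must be nonzero.
#' @param hemisphere \code{"left"} or \code{"right"}.
#' @return object of class \code{lead_placement} with unit \code{direction}.
#' @export
lead_placement <- function(tip, direction = c(0, 0, 1),
                           hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(length(tip) == 3, length(direction) == 3, all(is.finite(tip)))
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("`direction` must be nonzero")
  structure(list(tip = as.numeric(tip), direction = direction / nrm,
                 hemisphere = hemisphere), class = "lead_placement")
}

#' Stimulation configuration
#'
#' Monopolar cathodic stimulation; clinical defaults are 60 Hz frequency and
#' 90 microsecond pulse width, with amplitudes programmed up to 5 V.
#'
#' @param active_contacts integer contact indices in 0..n_contacts-1
#'   (C0 = 0); must be nonempty when amplitude > 0.
#' @param amplitude stimulation amplitude in volts (>= 0).
#' @param frequency Hz.
#' @param pulse_width microseconds.
#' @return object of class \code{stim_config}.
#' @export
stim_config <- function(active_contacts, amplitude, frequency = 60,
                        pulse_width = 90) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  active_contacts <- as.integer(active_contacts)
  if (amplitude > 0 && length(active_contacts) == 0L)
    stop("active_contacts must be nonempty when amplitude > 0")
  if (anyDuplicated(active_contacts)) stop("duplicate active contacts")
  structure(list(active_contacts = active_contacts,
                 amplitude = amplitude, frequency = frequency,
                 pulse_width = pulse_width, polarity = "monopolar_cathodic"),
            class = "stim_config")
}

#' Contact-centre world coordinates for a placed lead
#'
#' Centre of contact k is
#' \code{tip + (tip_to_first_contact + k*(contact_length + intercontact_gap)) * direction}.
#'
#' @param model a \code{lead_model}.
#' @param placement a \code{lead_placement}.
#' @return n_contacts x 3 matrix of world mm coordinates, rows named C0..;
#'   ordered C0 (most distal) outward along \code{direction}.
#' @export
contact_centers <- function(model, placement) {
  d <- placement$direction
  if (abs(sqrt(sum(d^2)) - 1) > 1e-9)
    stop("placement direction is not unit norm")
  k <- seq_len(model$n_contacts) - 1
  off <- model$tip_to_first_contact +
    k * (model$contact_length + model$intercontact_gap)
  ctr <- outer(off, d) + matrix(placement$tip, model$n_contacts, 3,
                                byrow = TRUE)
  rownames(ctr) <- paste0("C", k)
  ctr
}
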