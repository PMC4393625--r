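# Electrode geometry catalogue.  SEEG shafts carry 5-18 cylindrical
# platinum-iridium contacts, each 2 mm long and 0.8 mm in diameter, separated
# by a 1.5 mm gap between cylinder ends, i.e. a 3.5 mm centre-to-centre pitch.

#' Construct an electrode model
#'
#' The centre-to-centre contact spacing `d` is `contact_length + gap`:
#' the 1.5 mm "inter-contact distance" of the standard shaft is the gap
#' between cylinder ends (1.5 mm centre spacing would be physically
#' impossible for 2 mm cylinders), giving the canonical d = 3.5 mm.
#'
#' @param n_contacts Number of contacts, or `NA` when unknown (the
#'   segmentation then runs until signal loss).
#' @param contact_length Cylinder length in mm.
#' @param contact_diameter Cylinder diameter in mm.
#' @param gap End-to-end gap between consecutive cylinders in mm.
#' @return An object of class `electrode_model` with the derived
#'   centre-to-centre `spacing`.
#' @export
electrode_model <- function(n_contacts = NA_integer_, contact_length = 2,
                            contact_diameter = 0.8, gap = 1.5) {
  if (!is.na(n_contacts)) {
    if (!is.numeric(n_contacts) || length(n_contacts) != 1L ||
        n_contacts != round(n_contacts) || n_contacts < 1)
      stop("'n_contacts' must be a positive integer or NA", call. = FALSE)
    n_contacts <- as.integer(n_contacts)
  }
  for (v in c(contact_length, contact_diameter, gap))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("contact dimensions must be positive lengths in mm", call. = FALSE)
  structure(list(n_contacts = n_contacts,
                 contact_length = as.double(contact_length),
                 contact_diameter = as.double(contact_diameter),
                 gap = as.double(gap),
                 spacing = as.double(contact_length + gap)),
            class = "electrode_model")
}

#' Default catalogue electrode
#'
#' Standard SEEG shaft geometry with the requested contact count; catalogue
#' entries cover 5 to 18 contacts.
#'
#' @param n_contacts Integer in 5..18.
#' @return An [electrode_model()] with 2 mm x 0.8 mm contacts, 1.5 mm gap
#'   and 3.5 mm centre-to-centre spacing.
#' @export
default_model <- function(n_contacts) {
  if (!is.numeric(n_contacts) || length(n_contacts) != 1L ||
      n_contacts != round(n_contacts) || n_contacts < 5 || n_contacts > 18)
    stop("catalogue electrodes have between 5 and 18 contacts", call. = FALSE)
  electrode_model(n_contacts = as.integer(n_contacts))
}

#' @export
print.electrode_model <- function(x, ...) {
  cat(sprintf(
    "<electrode_model> %s contacts, %.1f x %.1f mm, gap %.1f mm (pitch d = %.1f mm)\n",
    ifelse(is.na(x$n_contacts), "?", x$n_contacts),
    x$contact_length, x$contact_diameter, x$gap, x$spacing))
  invisible(x)
}

#' Read an electrode-model configuration file
#'
#' Key-value text format, one electrode label per line:
#' `LABEL=n_contacts` or `LABEL=n_contacts,length,diameter,gap`.
#' The label `*` registers the default model applied to electrodes not
#' listed. `#` comments and blank lines are ignored.
#'
#' @param path Path to the configuration file.
#' @return Named list of [electrode_model()]s (possibly containing `"*"`).
#' @export
read_models_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("models config not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw) || startsWith(raw, "#")) next
    kv <- strsplit(raw, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L || !nzchar(trimws(kv[1])))
      stop(sprintf("%s: malformed line %d: '%s'", path, ln, raw),
           call. = FALSE)
    vals <- suppressWarnings(as.numeric(strsplit(kv[2], ",")[[1]]))
    if (!length(vals) %in% c(1L, 4L) || any(!is.finite(vals)))
      stop(sprintf("%s: malformed line %d: '%s'", path, ln, raw),
           call. = FALSE)
    m <- if (length(vals) == 1L) electrode_model(vals)
         else electrode_model(vals[1], vals[2], vals[3], vals[4])
    out[[trimws(kv[1])]] <- m
  }
  out
}

# model lookup for a given electrode label
.model_for_label <- function(models, label) {
  if (is.null(models)) return(electrode_model())
  if (inherits(models, "electrode_model")) return(models)
  if (!is.null(models[[label]])) return(models[[label]])
  if (!is.null(models[["*"]])) return(models[["*"]])
  electrode_model()
}
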