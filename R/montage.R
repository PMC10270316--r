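#' Standard 10-10 montage for the 64-channel willed-attention recordings
#'
#' Loads the electrode montage used throughout the package: 62 scalp sites of
#' the extended 10-20 (10-10) system plus the TP9/TP10 reference sites
#' adjacent to the mastoids, with unit-sphere coordinates. Named channel
#' groups give the analysis subsets:
#'
#' * `posterior_19` -- all parietal, parieto-occipital and occipital
#'   electrodes (the posterior decoding set),
#' * `central_19` -- a mirror-symmetric set of frontocentral, central and
#'   centroparietal electrodes (the mu-rhythm control set),
#' * `eye_proxy` -- FT9/FT10, used for the eye-movement rejector,
#' * `reference` -- TP9/TP10,
#' * `all_nonreference` -- every channel except the references.
#'
#' @param path Path to a montage TSV with columns `name`, `x`, `y`, `z`.
#'   Defaults to the 10-10 table shipped with the package.
#' @return A tibble of class `wd_montage` with columns `name`, `x`, `y`, `z`
#'   (unit-norm positions) and a `groups` attribute (named list of channel
#'   name vectors).
#' @export
default_montage <- function(path = system.file("extdata", "montage_1010.tsv",
                                               package = "willdecode")) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(), .default = readr::col_double()
  ))
  stopifnot(all(c("name", "x", "y", "z") %in% names(tab)))
  if (anyDuplicated(tab$name) > 0) {
    stop("montage contains duplicated channel names")
  }
  nrm <- sqrt(tab$x^2 + tab$y^2 + tab$z^2)
  tab$x <- tab$x / nrm
  tab$y <- tab$y / nrm
  tab$z <- tab$z / nrm

  groups <- list(
    posterior_19 = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
                     "PO9", "PO7", "PO3", "POz", "PO4", "PO8", "PO10",
                     "O1", "Oz", "O2"),
    central_19 = c("FC5", "FC3", "FC1", "FC2", "FC4", "FC6",
                   "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
                   "CP5", "CP3", "CP1", "CP2", "CP4", "CP6"),
    eye_proxy = c("FT9", "FT10"),
    reference = c("TP9", "TP10")
  )
  groups$all_nonreference <- setdiff(tab$name, groups$reference)
  missing <- setdiff(unlist(groups), tab$name)
  if (length(missing) > 0) {
    stop("montage is missing grouped channels: ", paste(missing, collapse = ", "))
  }
  structure(tibble::as_tibble(tab), groups = groups,
            class = c("wd_montage", class(tibble::tibble())))
}

#' Named channel groups of a montage
#' @param montage A `wd_montage`.
#' @return Named list of character vectors.
#' @export
montage_groups <- function(montage) attr(montage, "groups")

#' Resolve a channel-set name to channel labels
#'
#' @param montage A `wd_montage`.
#' @param set One of the group names (e.g. `"posterior_19"`) or a character
#'   vector of explicit channel labels.
#' @return Character vector of channel names.
#' @export
resolve_channel_set <- function(montage, set) {
  groups <- montage_groups(montage)
  if (length(set) == 1 && set %in% names(groups)) {
    return(groups[[set]])
  }
  unknown <- setdiff(set, montage$name)
  if (length(unknown) > 0) {
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  }
  set
}

#' Left/right mirror of 10-10 channel labels
#'
#' In the 10-10 naming scheme odd digits are left-hemisphere, even digits
#' right-hemisphere, and `z` sites lie on the midline. Swapping odd with even
#' (1<->2, 3<->4, ...) mirrors the montage about the midsagittal plane.
#'
#' @param names Character vector of channel labels.
#' @return The mirrored labels.
#' @export
mirror_channels <- function(names) {
  vapply(names, function(nm) {
    m <- regmatches(nm, regexpr("[0-9]+$", nm))
    if (length(m) == 0) return(nm)
    num <- as.integer(m)
    pre <- sub("[0-9]+$", "", nm)
    swapped <- if (num %% 2 == 1) num + 1L else num - 1L
    paste0(pre, swapped)
  }, character(1), USE.NAMES = FALSE)
}

#' Great-circle distances from one channel to all others
#' @noRd
channel_distances <- function(montage, focus_channel) {
  i <- match(focus_channel, montage$name)
  if (is.na(i)) stop("unknown channel label: ", focus_channel)
  p <- c(montage$x[i], montage$y[i], montage$z[i])
  dots <- montage$x * p[1] + montage$y * p[2] + montage$z * p[3]
  acos(pmin(1, pmax(-1, dots)))
}

#' Smooth scalp topography centred on a channel
#'
#' Gaussian-in-angle spatial profile used to mix simulated sources into the
#' montage: weight 1 at the focus channel, decaying monotonically with
#' great-circle distance.
#'
#' @param montage A `wd_montage`.
#' @param focus_channel Channel label at which the weight is exactly 1.
#' @param spread Angular scale in radians (> 0).
#' @return Named numeric vector of weights in `[0, 1]`, one per montage
#'   channel, in montage order.
#' @export
build_topography <- function(montage, focus_channel, spread) {
  stopifnot(is.numeric(spread), spread > 0)
  d <- channel_distances(montage, focus_channel)
  w <- exp(-0.5 * (d / spread)^2)
  names(w) <- montage$name
  w
}
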