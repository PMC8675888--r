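#' @include AllClasses.R
NULL

## Legacy 10-20 names -> modern 10-10 equivalents. Stored data always uses
## the canonical modern form (case-normalised, e.g. "FC3" not "Fc3").
.CHANNEL_ALIASES <- c(
  "T3" = "T7", "T4" = "T8", "T5" = "P7", "T6" = "P8"
)

## Canonical capitalisation for 10-10 labels: letters upper-case except the
## lower-case "z" midline marker and "p" in "Fp".
.canonicalCase <- function(x) {
  x <- toupper(x)
  x <- sub("Z", "z", x, fixed = TRUE)
  x <- sub("^FP", "Fp", x)
  x
}

#' Normalise EEG channel labels to canonical modern 10-10 names
#'
#' Upper/lower case is normalised (midline \code{z} and the \code{Fp} prefix
#' are lower-cased) and legacy 10-20 temporal labels (\code{T3}, \code{T4},
#' \code{T5}, \code{T6}) are mapped to their modern 10-10 equivalents
#' (\code{T7}, \code{T8}, \code{P7}, \code{P8}).
#'
#' @param labels character vector of channel labels.
#' @return character vector of canonical labels, same length.
#' @examples
#' canonicalChannels(c("T3", "FCZ", "fp1", "Oz"))
#' @export
canonicalChannels <- function(labels) {
  stopifnot(is.character(labels))
  out <- .canonicalCase(labels)
  hit <- out %in% names(.CHANNEL_ALIASES)
  out[hit] <- .CHANNEL_ALIASES[out[hit]]
  out
}

#' Default 31-channel 10-10 montage
#'
#' The 31-scalp-electrode montage used throughout the package as the default
#' recording layout, in canonical modern naming (legacy temporal labels
#' already mapped).
#'
#' @return character vector of 31 channel labels.
#' @examples
#' defaultMontage()
#' @export
defaultMontage <- function() {
  canonicalChannels(c(
    "Fp1", "Fpz", "Fp2", "F3", "Fz", "F4", "F7", "F8",
    "FC3", "FCz", "FC4", "FT7", "FT8", "C3", "Cz", "C4",
    "CP3", "CPz", "CP4", "P3", "Pz", "P4", "TP8", "TP7",
    "T3", "T4", "T5", "T6", "O1", "Oz", "O2"
  ))
}

## Approximate 2-D head-cap coordinates (unit head radius, nose up) for the
## channels the package works with. Used only by the synthetic generator to
## shape spatial topographies; features never need geometry.
.CHANNEL_XY <- local({
  m <- rbind(
    Fp1 = c(-0.31, 0.95), Fpz = c(0.00, 1.00), Fp2 = c(0.31, 0.95),
    F7  = c(-0.81, 0.59), F3  = c(-0.55, 0.68), Fz  = c(0.00, 0.72),
    F4  = c(0.55, 0.68),  F8  = c(0.81, 0.59),
    FT7 = c(-0.95, 0.31), FC3 = c(-0.56, 0.40), FCz = c(0.00, 0.38),
    FC4 = c(0.56, 0.40),  FT8 = c(0.95, 0.31),
    T7  = c(-1.00, 0.00), C3  = c(-0.58, 0.00), Cz  = c(0.00, 0.00),
    C4  = c(0.58, 0.00),  T8  = c(1.00, 0.00),
    TP7 = c(-0.95, -0.31), CP3 = c(-0.56, -0.40), CPz = c(0.00, -0.38),
    CP4 = c(0.56, -0.40), TP8 = c(0.95, -0.31),
    P7  = c(-0.81, -0.59), P3  = c(-0.55, -0.68), Pz  = c(0.00, -0.72),
    P4  = c(0.55, -0.68), P8  = c(0.81, -0.59),
    O1  = c(-0.31, -0.95), Oz  = c(0.00, -1.00), O2  = c(0.31, -0.95)
  )
  colnames(m) <- c("x", "y")
  m
})

#' Named electrode set
#'
#' Constructs a \linkS4class{ChannelSet}: a named collection of channel
#' labels used by the topographic features. Labels are normalised with
#' \code{\link{canonicalChannels}}.
#'
#' @param name single string naming the set.
#' @param members character vector of channel labels (non-empty).
#' @return a \linkS4class{ChannelSet}.
#' @examples
#' ChannelSet("left-eye", c("Fp1", "F7"))
#' @export
ChannelSet <- function(name, members) {
  new("ChannelSet", name = as.character(name),
      members = unique(canonicalChannels(members)))
}

#' Built-in electrode sets for the topographic features
#'
#' Returns the named electrode sets the spatial features rely on:
#' \describe{
#'   \item{mu}{fronto-central set for the mu-topography feature MT.}
#'   \item{alpha}{centro-parieto-occipital set for the alpha-topography
#'     feature AT. Note \code{C3}, \code{Cz}, \code{C4} belong to both.}
#'   \item{frontal, posterior}{regions contrasted by SAD and SVD.}
#'   \item{leftEye, rightEye}{periocular channels contrasted by SED.}
#' }
#'
#' @return named list of \linkS4class{ChannelSet} objects.
#' @examples
#' channelSets()$mu
#' @export
channelSets <- function() {
  list(
    mu = ChannelSet("mu", c("Fp1", "Fpz", "Fp2", "F3", "Fz", "F4",
                            "FC3", "FCz", "FC4", "C3", "Cz", "C4")),
    alpha = ChannelSet("alpha", c("C3", "Cz", "C4", "CP3", "CPz", "CP4",
                                  "P3", "Pz", "P4", "O1", "Oz", "O2")),
    frontal = ChannelSet("frontal", c("Fp1", "Fpz", "Fp2", "F3", "Fz",
                                      "F4", "F7", "F8")),
    posterior = ChannelSet("posterior", c("P3", "Pz", "P4", "O1", "Oz",
                                          "O2", "P7", "P8")),
    leftEye = ChannelSet("leftEye", c("Fp1", "F7")),
    rightEye = ChannelSet("rightEye", c("Fp2", "F8"))
  )
}

## Intersect a ChannelSet with a montage; drop absentees with a warning.
## Errors only when nothing is left.
.applySet <- function(set, montage, error = TRUE) {
  keep <- set@members[set@members %in% montage]
  missing <- setdiff(set@members, montage)
  if (length(missing))
    warning(sprintf("channel set '%s': dropping %s (not in montage)",
                    set@name, paste(missing, collapse = ", ")),
            call. = FALSE)
  if (!length(keep) && error)
    stop(sprintf("channel set '%s' has no members in the montage", set@name),
         call. = FALSE)
  keep
}
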