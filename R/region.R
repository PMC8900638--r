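# Region-weight configuration: four scalp regions (left/right anterior,
# left/right posterior) with fixed coefficient mass 0.4/0.3/0.2/0.1 split
# across the channels of each region. Higher-activation anterior regions get
# the larger coefficients.

# Printed channel lists for the two supported montages, after typo
# normalization (EP1->FP1, AP4->AF4, 01->O1, FC8->FT8, and the duplicated
# FC5 in SEED region 1 read as FC1). "C8" is kept as printed even though the
# extended 10-20 system calls that position T8.
.seed_regions <- list(
  `1` = c("FP1", "AF3", "F7", "F5", "F3", "F1", "FT7", "FC5", "FC3", "FC1",
          "T7", "C5", "C3", "C1"),
  `2` = c("FP2", "AF4", "F2", "F4", "F6", "F8", "FC2", "FC4", "FC6", "FT8",
          "FPZ", "FZ", "FCZ", "CZ"),
  `3` = c("TP7", "CP5", "CP3", "CP1", "P7", "P5", "P3", "P1", "PO7", "PO5",
          "PO3", "CB1", "O1", "CPZ", "PZ", "POZ", "OZ"),
  `4` = c("CP2", "CP4", "CP6", "TP8", "P2", "P4", "P6", "P8", "PO4", "PO6",
          "PO8", "CB2", "O2", "C2", "C4", "C6", "C8"))

.deap_regions <- list(
  `1` = c("FP1", "AF3", "F7", "F3", "FC5", "FC1", "T7", "C3"),
  `2` = c("FP2", "AF4", "F4", "F8", "FC2", "FC6", "FZ", "CZ"),
  `3` = c("CP5", "CP1", "P7", "P3", "PO3", "O1", "PZ", "OZ"),
  `4` = c("CP2", "CP6", "P4", "P8", "PO4", "O2", "C4", "T8"))

.region_sums <- c(`1` = 0.4, `2` = 0.3, `3` = 0.2, `4` = 0.1)

.norm_channel <- function(x) toupper(gsub("[[:space:]]+", "", x))

#' Region weighting of a montage
#'
#' Maps each channel to one of four scalp regions and attaches the total
#' coefficient mass of each region. The built-in presets reproduce the
#' four-region division of the 62-channel (SEED-like) and 32-channel
#' (DEAP-like) montages with region sums 0.4, 0.3, 0.2 and 0.1 for the left
#' anterior, right anterior, left posterior and right posterior regions.
#'
#' Channel-name matching is case-insensitive and ignores whitespace. If a
#' channel is listed under more than one region it is assigned to the first
#' region listing it.
#'
#' @param config optional path to a key-value text file with lines
#'   `CHANNEL=REGION` (region in 1..4) and `region_sum.R=VALUE`; overrides the
#'   preset when given.
#' @param dataset `"seed"` or `"deap"`, selecting the built-in preset.
#' @return An object of class `region_weighting` with `region_of_channel`
#'   (named integer vector) and `region_sum` (numeric of length 4).
#' @examples
#' w <- load_region_weighting(dataset = "seed")
#' sum(w$region_sum)
#' @export
load_region_weighting <- function(config = NULL, dataset = c("seed", "deap")) {
  if (is.null(config)) {
    dataset <- match.arg(dataset)
    regions <- if (dataset == "seed") .seed_regions else .deap_regions
    roc <- integer(0)
    for (r in names(regions)) {
      new <- setdiff(regions[[r]], names(roc))  # first region listing wins
      roc[new] <- as.integer(r)
    }
    return(region_weighting(roc, .region_sums))
  }
  if (!file.exists(config)) stop_io(sprintf("config file not found: %s", config))
  lines <- readLines(config, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop_config(sprintf("unparseable config line: '%s'",
                                    lines[which(bad)[1L]]))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  is_sum <- startsWith(keys, "region_sum.")
  region_sum <- .region_sums
  if (any(is_sum)) {
    ids <- sub("^region_sum\\.", "", keys[is_sum])
    region_sum <- numeric(0)
    region_sum[ids] <- as.numeric(vals[is_sum])
  }
  roc <- as.integer(vals[!is_sum])
  names(roc) <- .norm_channel(keys[!is_sum])
  if (anyNA(roc)) stop_config("channel regions must be integers")
  region_weighting(roc, region_sum)
}

#' @rdname load_region_weighting
#' @param region_of_channel named integer vector, channel name -> region id.
#' @param region_sum named numeric vector of per-region coefficient sums;
#'   must total 1.
#' @export
region_weighting <- function(region_of_channel, region_sum) {
  names(region_of_channel) <- .norm_channel(names(region_of_channel))
  if (anyDuplicated(names(region_of_channel)))
    stop_validation("each channel must map to exactly one region")
  if (is.null(names(region_sum)))
    names(region_sum) <- seq_along(region_sum)
  if (any(region_sum < 0))
    stop_validation("region coefficient sums must be nonnegative")
  if (abs(sum(region_sum) - 1) > 1e-12)
    stop_validation(sprintf(
      "region coefficient sums must total 1 (got %.15g)", sum(region_sum)))
  if (!all(as.character(region_of_channel) %in% names(region_sum)))
    stop_validation("a channel refers to a region with no coefficient sum")
  structure(list(region_of_channel = region_of_channel,
                 region_sum = region_sum),
            class = "region_weighting")
}

#' @export
print.region_weighting <- function(x, ...) {
  cat(sprintf("<region_weighting> %d channels in %d regions\n",
              length(x$region_of_channel), length(x$region_sum)))
  for (r in names(x$region_sum))
    cat(sprintf("  region %s (sum %.3g): %s\n", r, x$region_sum[[r]],
                paste(names(x$region_of_channel)[x$region_of_channel == r],
                      collapse = ",")))
  invisible(x)
}
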