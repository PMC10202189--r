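#' Growth factor vocabulary and default decoder map
#'
#' The simulator abstracts the crop as "one big organ" per organ type: all
#' leaves, stem segments, petioles and harvested fruits of a plant are summed
#' into per-plant totals. The daily growth state is a fixed set of 21 factors
#' in six groups, each group predicted by its own decoder:
#' \describe{
#'   \item{status}{total cumulative radiation (MJ m-2), cumulative growing
#'     degree days -- quantities recomputable from the environment alone.}
#'   \item{property}{plant height (m), maximum number of nodes per stem.}
#'   \item{leaf}{leaf area (m2), leaf count, fresh weight (g), dry weight (g).}
#'   \item{stem}{summed node length (cm), summed node diameter (mm), stem
#'     count, fresh weight (g), dry weight (g).}
#'   \item{petiole}{count, fresh weight (g), dry weight (g).}
#'   \item{harvest}{summed fruit height (cm), summed fruit width (cm),
#'     cumulative fruit count, cumulative fresh weight (g), cumulative dry
#'     weight (g).}
#' }
#'
#' @return A data.frame with columns `name`, `group` and `cumulative`
#'   (logical; `TRUE` for factors that are non-decreasing in time by
#'   definition: the status totals and the harvest factors).
#' @export
#' @examples
#' crop_factors()
crop_factors <- function() {
  df <- rbind(
    data.frame(name = c("cum_radiation", "cum_gdd"), group = "status"),
    data.frame(name = c("plant_height", "max_nodes"), group = "property"),
    data.frame(name = c("leaf_area", "leaf_count", "leaf_fw", "leaf_dw"),
               group = "leaf"),
    data.frame(name = c("node_length", "node_diameter", "stem_count",
                        "stem_fw", "stem_dw"), group = "stem"),
    data.frame(name = c("petiole_count", "petiole_fw", "petiole_dw"),
               group = "petiole"),
    data.frame(name = c("fruit_height", "fruit_width", "harvest_count",
                        "harvest_fw", "harvest_dw"), group = "harvest")
  )
  df$cumulative <- df$group %in% c("status", "harvest")
  df
}

#' Default decoder-to-factor mapping
#'
#' Six structurally identical decoders share one encoder; each owns a disjoint
#' group of growth factors. The mapping is configurable but must always cover
#' every configured factor exactly once.
#'
#' @param factors Factor table as returned by [crop_factors()].
#' @return Named list mapping decoder name to integer factor indices.
#' @export
default_decoder_map <- function(factors = crop_factors()) {
  groups <- c("status", "property", "leaf", "stem", "petiole", "harvest")
  m <- lapply(groups, function(g) which(factors$group == g))
  names(m) <- groups
  m
}

# validate a decoder map against a factor table: disjoint cover
check_decoder_map <- function(decoder_map, n_factors) {
  idx <- unlist(decoder_map, use.names = FALSE)
  if (length(decoder_map) < 1L)
    stop("decoder_map must contain at least one decoder")
  if (anyDuplicated(idx))
    stop("decoder_map factor sets must be disjoint")
  if (!setequal(idx, seq_len(n_factors)))
    stop("decoder_map must cover all ", n_factors, " factors exactly once")
  invisible(TRUE)
}

# names of the vegetative fresh/dry weight factors entering the two
# conservation loss terms (total vegetative FW/DW = leaf + stem + petiole)
veg_fw_factors <- function() c("leaf_fw", "stem_fw", "petiole_fw")
veg_dw_factors <- function() c("leaf_dw", "stem_dw", "petiole_dw")

#' Fixed model-input feature order
#'
#' The seven encoder input features, in fixed column order. The first three
#' vary hourly; the last four are daily values broadcast to all 24 hours of
#' their day.
#'
#' @return Character vector of feature names.
#' @export
env_feature_names <- function() {
  c("temperature", "relative_humidity", "radiation",
    "dif", "daily_cum_radiation", "cum_gdd", "daily_vpd")
}
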