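#' Network atlas: ROI -> resting-state network assignment
#'
#' An atlas maps each region of interest (ROI) to exactly one of the three
#' large-scale resting-state networks considered by the pipeline: the default
#' mode network (DMN), the salience network (SN) and the frontoparietal
#' network (FPN). ROI order is meaningful: time-series columns must follow it.
#'
#' @param roi_names character vector of ROI identifiers, in column order.
#' @param networks character vector, same length, each one of
#'   `"DMN"`, `"SN"`, `"FPN"`.
#' @return An object of class `network_atlas` with elements `roi_names`,
#'   `network_of` (named character vector) and `network_sizes`.
#' @examples
#' atlas <- network_atlas(c("mPFC", "PCC", "dACC"), c("DMN", "DMN", "SN"))
#' atlas$network_sizes
#' @export
network_atlas <- function(roi_names, networks) {
  roi_names <- as.character(roi_names)
  networks <- as.character(networks)
  if (length(roi_names) != length(networks))
    stop("roi_names and networks must have the same length")
  if (length(roi_names) < 1L) stop("atlas must contain at least one ROI")
  dup <- roi_names[duplicated(roi_names)]
  if (length(dup))
    stop("duplicate ROI in atlas: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(networks), valid_networks())
  if (length(bad))
    stop("unknown network label: ", paste(bad, collapse = ", "),
         " (expected one of ", paste(valid_networks(), collapse = ", "), ")")
  network_of <- stats::setNames(networks, roi_names)
  sizes <- table(factor(networks, levels = valid_networks()))
  structure(
    list(roi_names = roi_names,
         network_of = network_of,
         network_sizes = stats::setNames(as.integer(sizes), names(sizes))),
    class = "network_atlas")
}

valid_networks <- function() c("DMN", "SN", "FPN")

#' @export
print.network_atlas <- function(x, ...) {
  cat("network_atlas:", length(x$roi_names), "ROIs (",
      paste(sprintf("%s=%d", names(x$network_sizes), x$network_sizes),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Read a network atlas from a delimited file
#'
#' The file must contain columns `roi` and `network` (header required,
#' comma- or tab-delimited, auto-detected).
#'
#' @param path path to the atlas file.
#' @return A [network_atlas()].
#' @export
read_atlas <- function(path) {
  df <- read_delimited(path)
  need <- c("roi", "network")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("atlas file missing column(s): ", paste(miss, collapse = ", "))
  network_atlas(df$roi, df$network)
}

#' The 11-ROI study atlas (DMN = 2, SN = 5, FPN = 4)
#'
#' Key cortical/subcortical nodes of the triple-network model: medial
#' prefrontal cortex and posterior cingulate (DMN); bilateral anterior insula,
#' dorsal anterior cingulate and bilateral nucleus accumbens (SN); bilateral
#' dorsolateral prefrontal cortex and bilateral intraparietal sulcus (FPN).
#'
#' @return A [network_atlas()] with 11 ROIs.
#' @export
default_atlas <- function() {
  path <- system.file("extdata", "atlas_dmn_sn_fpn.csv", package = "netgimme")
  if (nzchar(path)) return(read_atlas(path))
  # fallback when called from a source tree
  network_atlas(
    c("mPFC", "PCC",
      "L_AI", "R_AI", "dACC", "L_NAcc", "R_NAcc",
      "L_dlPFC", "R_dlPFC", "L_IPS", "R_IPS"),
    c("DMN", "DMN", rep("SN", 5), rep("FPN", 4)))
}

# comma/tab auto-detection on the header line
read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}
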