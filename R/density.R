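density_categories <- function() {
  c("DMN-DMN", "SN-SN", "FPN-FPN", "DMN-SN", "SN-FPN", "DMN-FPN")
}

#' Names of the 12 sign-split density metrics
#' @return Character vector, within-network categories first.
#' @export
density_metric_names <- function() {
  as.vector(t(outer(density_categories(), c("pos", "neg"), paste, sep = "_")))
}

category_of <- function(net1, net2) {
  for (cat in density_categories()) {
    nets <- strsplit(cat, "-", fixed = TRUE)[[1]]
    if (setequal(c(net1, net2), nets) ||
        (net1 == net2 && nets[1] == nets[2] && nets[1] == net1))
      return(cat)
  }
  stop("no density category for networks ", net1, "/", net2)
}

# admissible directed non-AR path count per category:
# within a network of size n: contemporaneous n(n-1) + lagged non-self n(n-1)
# between networks of sizes n1, n2: (contemporaneous + lagged) x 2 directions
possible_paths <- function(atlas) {
  sz <- atlas$network_sizes
  vapply(density_categories(), function(cat) {
    nets <- strsplit(cat, "-", fixed = TRUE)[[1]]
    if (nets[1] == nets[2]) {
      n <- sz[[nets[1]]]
      2 * n * (n - 1)
    } else {
      4 * sz[[nets[1]]] * sz[[nets[2]]]
    }
  }, numeric(1))
}

#' Sign-split within/between-network density profile of one directed graph
#'
#' Each non-AR edge (AR = lag-1 self-loops, which every subject has by
#' construction and which carry no between-subject information) is assigned
#' to the unordered pair of networks of its endpoints and to the sign of its
#' estimate, giving 12 categories: {DMN-DMN, SN-SN, FPN-FPN, DMN-SN, SN-FPN,
#' DMN-FPN} x {positive, negative}. Density is the category count divided by
#' a denominator: mode `"possible"` (default) uses the number of admissible
#' directed non-AR paths in that category; mode `"total"` uses the subject's
#' total non-AR edge count, so the 12 values sum to 1.
#'
#' @param graph data.frame with columns `source`, `target` (ROI names or
#'   indices), `lag` (0/1) and `estimate` (nonzero).
#' @param atlas a [network_atlas()].
#' @param mode `"possible"` or `"total"`.
#' @param subject_id optional identifier carried through.
#' @return An object of class `density_profile`: named `values`, `counts`,
#'   `denominators`, plus `mode` and `subject_id`.
#' @export
compute_density_profile <- function(graph, atlas,
                                    mode = c("possible", "total"),
                                    subject_id = NA_character_) {
  mode <- match.arg(mode)
  if (!"estimate" %in% names(graph) && "coefficient" %in% names(graph))
    graph$estimate <- graph$coefficient
  metrics <- density_metric_names()
  counts <- stats::setNames(numeric(length(metrics)), metrics)
  if (nrow(graph)) {
    src <- graph$source; tgt <- graph$target
    if (is.numeric(src)) src <- atlas$roi_names[src]
    if (is.numeric(tgt)) tgt <- atlas$roi_names[tgt]
    ar <- graph$lag == 1 & src == tgt
    g <- graph[!ar, , drop = FALSE]; src <- src[!ar]; tgt <- tgt[!ar]
    if (nrow(g) && any(g$estimate == 0))
      stop("edge with zero estimate: sign undefined")
    for (k in seq_len(nrow(g))) {
      cat_ <- category_of(atlas$network_of[[src[k]]],
                          atlas$network_of[[tgt[k]]])
      sgn <- if (g$estimate[k] > 0) "pos" else "neg"
      m <- paste(cat_, sgn, sep = "_")
      counts[m] <- counts[m] + 1
    }
  }
  denom <- if (mode == "possible") {
    rep(possible_paths(atlas), each = 2)
  } else {
    rep(max(sum(counts), 1), length(metrics))
  }
  denom <- stats::setNames(denom, metrics)
  values <- counts / denom
  structure(list(values = values, counts = counts, denominators = denom,
                 mode = mode, subject_id = subject_id),
            class = "density_profile")
}

#' Cohort density table
#'
#' @param profiles list of `density_profile` objects.
#' @return data.frame: one row per subject, `subject_id` plus the 12 metrics.
#' @export
density_table <- function(profiles) {
  vals <- do.call(rbind, lapply(profiles, function(pr) pr$values))
  df <- data.frame(subject_id = vapply(profiles, function(pr)
    as.character(pr$subject_id), character(1)), vals,
    check.names = FALSE)
  rownames(df) <- NULL
  df
}

#' Table-2-style cohort summary of density metrics
#'
#' @param profiles list of `density_profile` objects.
#' @return data.frame with per-metric nonzero-subject count, mean, sd, range.
#' @export
density_summary <- function(profiles) {
  tab <- density_table(profiles)
  m <- as.matrix(tab[density_metric_names()])
  data.frame(metric = density_metric_names(),
             n_nonzero = colSums(m > 0),
             mean = colMeans(m),
             sd = apply(m, 2, stats::sd),
             min = apply(m, 2, min),
             max = apply(m, 2, max),
             row.names = NULL)
}

#' Apply the 25 percent-of-sample eligibility rule
#'
#' A density metric enters the outcome regressions only if at least
#' `ceiling(threshold * N)` subjects have a nonzero value for it.
#'
#' @param profiles list of `density_profile` objects (or a [density_table()]
#'   data.frame).
#' @param threshold fraction of the sample required (default 0.25).
#' @return List of class `eligibility_set`: named logical `included`,
#'   `n_nonzero`, `min_n`, `threshold`.
#' @export
eligible_metrics <- function(profiles, threshold = 0.25) {
  tab <- if (is.data.frame(profiles)) profiles else density_table(profiles)
  m <- as.matrix(tab[density_metric_names()])
  N <- nrow(m)
  stopifnot(N >= 1)
  min_n <- ceiling(threshold * N)
  n_nonzero <- colSums(m > 0)
  structure(list(included = n_nonzero >= min_n, n_nonzero = n_nonzero,
                 min_n = min_n, threshold = threshold, N = N),
            class = "eligibility_set")
}
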