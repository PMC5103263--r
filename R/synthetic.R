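#' @include AllClasses.R
NULL

#' Random directed graph with tunable reciprocity
#'
#' Each unordered vertex pair is independently connected with probability
#' \code{pArc}; a connected pair becomes a reciprocal edge with
#' probability \code{pRec} and otherwise a pure arc with uniform
#' orientation. Deterministic under \code{seed}.
#'
#' @param n Number of vertices.
#' @param pArc Probability in [0, 1] that a pair is connected.
#' @param pRec Conditional probability in [0, 1] that a connected pair is
#'   reciprocal.
#' @param seed Optional integer seed.
#' @param labels Optional vertex labels (default \code{v1..vn}).
#' @return A \code{\link{DirectedNetwork-class}}.
#' @export
#' @examples
#' randomDigraph(10, pArc = 0.3, pRec = 0.5, seed = 1)
randomDigraph <- function(n, pArc, pRec, seed = NULL, labels = NULL) {
  if (pArc < 0 || pArc > 1 || pRec < 0 || pRec > 1)
    stop("pArc and pRec must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- paste0("v", seq_len(n))
  if (n < 2L)
    return(DirectedNetwork(labels = labels))
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  connected <- stats::runif(nrow(pr)) < pArc
  pr <- pr[connected, , drop = FALSE]
  if (nrow(pr) == 0L)
    return(DirectedNetwork(labels = labels))
  rec <- stats::runif(nrow(pr)) < pRec
  fwd <- stats::runif(nrow(pr)) < 0.5
  from <- c(pr[rec, 1L], pr[rec, 2L],
            pr[!rec & fwd, 1L], pr[!rec & !fwd, 2L])
  to <- c(pr[rec, 2L], pr[rec, 1L],
          pr[!rec & fwd, 2L], pr[!rec & !fwd, 1L])
  DirectedNetwork(cbind(from, to), labels = labels)
}

#' Synthetic signed weighted cohort emulating GCA connectivity
#'
#' Generates one dense signed weight matrix per subject, emulating the
#' output of ROI-wise multivariate Granger-causality analysis on
#' resting-state fMRI: heavy-tailed (lognormal) weight magnitudes, a
#' fixed fraction of positive (excitatory) entries, a few planted
#' out-hub regions with inflated outgoing magnitudes to induce realistic
#' degree heterogeneity after pruning, and a cohort-shared base structure
#' plus independent per-subject lognormal noise so that cohort consensus
#' has signal to find.
#'
#' @param nRegions Number of regions (vertices); default 116 (the AAL
#'   atlas size the method targets).
#' @param subjects Cohort size; default 40.
#' @param seed Integer seed (required: cohorts must be reproducible).
#' @param sdLog Lognormal sigma of the base weight magnitudes; default 1.
#' @param signFraction Fraction of entries with positive sign; default
#'   0.6.
#' @param noiseSd Standard deviation of the per-subject perturbation of
#'   the log-magnitudes; default 0.4.
#' @param hubs Number of planted out-hub regions; default 6.
#' @param hubBoost Additive log-magnitude boost of hub rows; default 1.5.
#' @return List of \code{\link{SignedWeightedNetwork-class}} objects,
#'   named \code{sub01, sub02, ...}; the planted hub regions are attached
#'   as attribute \code{"hubs"}.
#' @export
gcaCohort <- function(nRegions = 116L, subjects = 40L, seed,
                      sdLog = 1.0, signFraction = 0.6, noiseSd = 0.4,
                      hubs = 6L, hubBoost = 1.5) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible cohorts", call. = FALSE)
  if (signFraction < 0 || signFraction > 1)
    stop("signFraction must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  n <- as.integer(nRegions)
  labels <- sprintf("ROI%03d", seq_len(n))
  off <- row(matrix(0, n, n)) != col(matrix(0, n, n))
  baseLog <- matrix(stats::rnorm(n * n, sd = sdLog), n, n)
  signs <- matrix(ifelse(stats::runif(n * n) < signFraction, 1, -1), n, n)
  hubRows <- if (hubs > 0L) sample.int(n, min(hubs, n)) else integer()
  baseLog[hubRows, ] <- baseLog[hubRows, , drop = FALSE] + hubBoost
  out <- vector("list", subjects)
  for (s in seq_len(subjects)) {
    noise <- matrix(stats::rnorm(n * n, sd = noiseSd), n, n)
    w <- signs * exp(baseLog + noise)
    w[!off] <- 0
    dimnames(w) <- list(labels, labels)
    out[[s]] <- SignedWeightedNetwork(w)
  }
  names(out) <- sprintf("sub%02d", seq_len(subjects))
  attr(out, "hubs") <- labels[hubRows]
  out
}

#' Write a synthetic cohort to disk with a manifest
#'
#' Writes one signed weight CSV per subject plus a TSV manifest of
#' (\code{subject_id}, \code{excitatory_path}, \code{inhibitory_path})
#' referencing the sign-split halves, in the dialect read by
#' \code{\link{readCohortManifest}}.
#'
#' @param cohort List of \code{SignedWeightedNetwork} objects (as from
#'   \code{\link{gcaCohort}}).
#' @param dir Output directory (created if needed).
#' @param connectFraction,degreeFactor Pruning parameters forwarded to
#'   \code{\link{pruneNetwork}}.
#' @return Invisibly, the manifest path.
#' @export
writeCohortDirectory <- function(cohort, dir, connectFraction = 0.99,
                                 degreeFactor = 2.0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(cohort)
  if (is.null(ids)) ids <- sprintf("sub%02d", seq_along(cohort))
  rows <- lapply(seq_along(cohort), function(s) {
    halves <- splitBySign(cohort[[s]])
    paths <- c(excitatory = paste0(ids[s], "_exc.tsv"),
               inhibitory = paste0(ids[s], "_inh.tsv"))
    for (h in names(paths)) {
      pruned <- pruneNetwork(halves[[h]],
                             connectFraction = connectFraction,
                             degreeFactor = degreeFactor)
      writeNetwork(pruned$network, file.path(dir, paths[h]))
    }
    data.frame(subject_id = ids[s], excitatory_path = paths[["excitatory"]],
               inhibitory_path = paths[["inhibitory"]])
  })
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
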