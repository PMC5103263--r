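#' @include gcm.R
NULL

#' Cohort consensus of significant graphlet correlations
#'
#' For every entry of the 16 x 16 graphlet correlation matrix, the
#' percentage of subjects whose coefficient is significantly positive
#' (above \code{threshold}) and the percentage with a significantly
#' negative one (below \code{-threshold}). A subject whose entry is
#' undefined (zero-variance column) counts as not significant there; the
#' denominator stays fixed at the cohort size.
#'
#' @param gcms List of \code{\link{GraphletCorrelationMatrix-class}}
#'   objects, one per subject.
#' @param threshold Correlation-magnitude significance threshold;
#'   default 0.7.
#' @return A \code{\link{ConsensusMatrix-class}}.
#' @export
#' @seealso \code{\link{consensusMask}}
consensus <- function(gcms, threshold = 0.7) {
  if (length(gcms) < 1L)
    stop("at least one subject GCM is required", call. = FALSE)
  ok <- vapply(gcms, function(g) is(g, "GraphletCorrelationMatrix"),
               logical(1L))
  if (!all(ok))
    stop("gcms must be a list of GraphletCorrelationMatrix objects",
         call. = FALSE)
  pos <- matrix(0, 16L, 16L,
                dimnames = list(.SIGNATURE_NAMES, .SIGNATURE_NAMES))
  neg <- pos
  for (g in gcms) {
    m <- significanceMask(g, threshold = threshold)
    pos <- pos + (m == 1L)
    neg <- neg + (m == -1L)
  }
  S <- length(gcms)
  new("ConsensusMatrix", positivePercent = 100 * pos / S,
      negativePercent = 100 * neg / S, nSubjects = as.integer(S),
      threshold = threshold)
}

#' Ternary consensus mask
#'
#' \code{+1} where the positive-consensus percentage is strictly greater
#' than \code{minPercent}, \code{-1} where the negative one is, \code{0}
#' otherwise ("more than" is a strict inequality; exactly
#' \code{minPercent} does not qualify).
#'
#' @param x A \code{ConsensusMatrix}.
#' @param minPercent Minimum percentage of subjects, in (0, 100];
#'   default 60.
#' @return Integer 16 x 16 matrix with entries in \code{-1, 0, +1}.
#' @export
consensusMask <- function(x, minPercent = 60) {
  stopifnot(is(x, "ConsensusMatrix"))
  if (!is.numeric(minPercent) || length(minPercent) != 1L ||
      minPercent <= 0 || minPercent > 100)
    stop("minPercent must be a single percentage in (0, 100]",
         call. = FALSE)
  m <- matrix(0L, 16L, 16L, dimnames = dimnames(x@positivePercent))
  m[x@positivePercent > minPercent] <- 1L
  m[x@negativePercent > minPercent] <- -1L
  m
}

#' Build a cohort record
#'
#' One subject's pair of binary directed networks — excitatory (from
#' positive causal coefficients) and inhibitory (from negative ones) — on
#' a shared labeled vertex set.
#'
#' @param subject Subject identifier.
#' @param excitatory,inhibitory \code{DirectedNetwork} objects with
#'   identical vertex label sets.
#' @return A list of class \code{"CohortRecord"}.
#' @export
cohortRecord <- function(subject, excitatory, inhibitory) {
  stopifnot(is(excitatory, "DirectedNetwork"),
            is(inhibitory, "DirectedNetwork"))
  if (!setequal(vertexLabels(excitatory), vertexLabels(inhibitory)))
    stop("excitatory and inhibitory networks must share one vertex set",
         call. = FALSE)
  structure(list(subject = as.character(subject),
                 excitatory = excitatory, inhibitory = inhibitory),
            class = "CohortRecord")
}

#' Regional comparison of a graphlet class between network conditions
#'
#' For a chosen signature coordinate (e.g. \code{"W_out"}), computes per
#' region the across-subject mean difference
#' \eqn{\Delta = } inhibitory count \eqn{-} excitatory count, and labels
#' regions where the difference is significant at level \code{alpha}:
#' \emph{greater-in-inhibitory} or \emph{greater-in-excitatory}. Two
#' confidence-interval strategies are available:
#' \describe{
#'   \item{\code{"region"} (default)}{per-region across-subject
#'     Student-t confidence interval of the mean difference; a region is
#'     labeled when its interval excludes zero. With \eqn{\ge 2} subjects
#'     this tests each region's own difference.}
#'   \item{\code{"population"}}{one normal-approximation interval
#'     \eqn{\mathrm{mean} \pm z_{1-\alpha/2}\,\mathrm{sd}} of the
#'     across-region distribution of mean differences; regions outside it
#'     are labeled. By construction this can flag at most a small
#'     fraction of regions (Chebyshev bounds it by \eqn{1/z^2}).}
#' }
#'
#' @param cohort List of \code{\link{cohortRecord}} objects (\eqn{\ge 2}
#'   subjects).
#' @param class One of \code{\link{signatureClassNames}}; default
#'   \code{"W_out"}.
#' @param alpha Two-sided significance level; default 0.05.
#' @param strategy Confidence-interval strategy, see Details.
#' @return List with \code{table} (data frame: region, meanDelta, lower,
#'   upper, verdict), \code{percentInhibitoryGreater},
#'   \code{percentExcitatoryGreater}, and the resolved \code{strategy}.
#' @export
regionalClassComparison <- function(cohort, class = "W_out", alpha = 0.05,
                                    strategy = c("region", "population")) {
  strategy <- match.arg(strategy)
  if (length(cohort) < 2L)
    stop("at least two subjects are required", call. = FALSE)
  if (!(class %in% .SIGNATURE_NAMES))
    stop("unknown signature class: ", class, call. = FALSE)
  labels <- vertexLabels(cohort[[1L]]$excitatory)
  S <- length(cohort)
  R <- length(labels)
  delta <- matrix(NA_real_, R, S, dimnames = list(labels, NULL))
  for (s in seq_len(S)) {
    rec <- cohort[[s]]
    if (!setequal(vertexLabels(rec$excitatory), labels) ||
        !setequal(vertexLabels(rec$inhibitory), labels))
      stop("all subjects must share one vertex label set", call. = FALSE)
    exc <- signatureCounts(signatureMatrix(rec$excitatory))[labels, class]
    inh <- signatureCounts(signatureMatrix(rec$inhibitory))[labels, class]
    delta[, s] <- inh - exc
  }
  meanDelta <- rowMeans(delta)
  verdict <- rep("none", R)
  if (strategy == "region") {
    sdDelta <- apply(delta, 1L, stats::sd)
    se <- sdDelta / sqrt(S)
    tcrit <- stats::qt(1 - alpha / 2, df = S - 1L)
    lower <- meanDelta - tcrit * se
    upper <- meanDelta + tcrit * se
    ## degenerate (zero-variance) regions: CI collapses to the mean
    verdict[lower > 0] <- "greater_in_inhibitory"
    verdict[upper < 0] <- "greater_in_excitatory"
    zeroSd <- se == 0
    verdict[zeroSd & meanDelta > 0] <- "greater_in_inhibitory"
    verdict[zeroSd & meanDelta < 0] <- "greater_in_excitatory"
    verdict[zeroSd & meanDelta == 0] <- "none"
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    mu <- mean(meanDelta)
    sdv <- stats::sd(meanDelta)
    lower <- rep(mu - z * sdv, R)
    upper <- rep(mu + z * sdv, R)
    verdict[meanDelta > upper] <- "greater_in_inhibitory"
    verdict[meanDelta < lower] <- "greater_in_excitatory"
  }
  tbl <- data.frame(region = labels, meanDelta = meanDelta,
                    lower = lower, upper = upper, verdict = verdict,
                    row.names = NULL)
  list(table = tbl,
       percentInhibitoryGreater =
         100 * mean(verdict == "greater_in_inhibitory"),
       percentExcitatoryGreater =
         100 * mean(verdict == "greater_in_excitatory"),
       strategy = strategy)
}

#' Read a cohort manifest
#'
#' TSV with columns \code{subject_id}, \code{excitatory_path},
#' \code{inhibitory_path} (paths resolved relative to the manifest's
#' directory; edge-list \code{.tsv} or adjacency/weight \code{.csv}).
#'
#' @param path Manifest path.
#' @return List of \code{\link{cohortRecord}} objects.
#' @export
readCohortManifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject_id", "excitatory_path", "inhibitory_path")
  if (!all(need %in% colnames(df)))
    stop("cohort manifest must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  base <- dirname(normalizePath(path))
  loadNet <- function(p) {
    if (!file.exists(p)) p <- file.path(base, p)
    if (grepl("\\.csv$", p, ignore.case = TRUE)) readAdjacencyMatrix(p)
    else readEdgeList(p)
  }
  lapply(seq_len(nrow(df)), function(k)
    cohortRecord(df$subject_id[k],
                 loadNet(df$excitatory_path[k]),
                 loadNet(df$inhibitory_path[k])))
}
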