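#' Per-sample mutation-status flags
#'
#' Flags each sample of a roster TRUE when it carries at least one mutation
#' of the requested class. Classes mirror the outcome stratifications:
#' \code{"mtDNA"} (any), \code{"protein-coding"}, \code{"nonsynonymous"},
#' \code{"high-VAF"} (VAF > 50\%), \code{"high-VAF-nonsynonymous"},
#' \code{"mtCTR"}, \code{"mtCDR"}, \code{"HVS"}, \code{"tRNA"}, \code{"rRNA"}.
#'
#' @param ann annotated mutation data.frame (see [annotateMutations()])
#' @param sampleIds full cohort roster (zero-mutation samples included)
#' @param what class name, or a character vector of classes
#' @return logical vector (one class) or data.frame of flags keyed by sample
#' @examples
#' # a VAF 0.6 nonsynonymous call flags high-VAF-nonsynonymous
#' @export
stratifySamples <- function(ann, sampleIds, what = "mtDNA") {
    one <- function(w) {
        sel <- .mutationSelector(ann, w)
        sampleIds %in% ann$sample_id[sel]
    }
    if (length(what) == 1L) return(one(what))
    out <- data.frame(sample_id = sampleIds, stringsAsFactors = FALSE)
    for (w in what) out[[w]] <- one(w)
    out
}

#' Kaplan-Meier product-limit estimator
#'
#' Right-continuous step survival function with S(0) = 1; ties and censoring
#' at an event time are handled in the standard way (censored subjects remain
#' at risk through that time).
#'
#' @param time follow-up times (>= 0)
#' @param event 1 = death, 0 = censored
#' @return data.frame(time, n_risk, n_event, surv) at the event times, with
#'   the underlying \code{survival::survfit} object as attribute \code{"fit"}
#' @export
kmEstimator <- function(time, event) {
    if (!length(time)) stop("empty input")
    stopifnot(all(time >= 0), length(time) == length(event))
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv)
    attr(out, "fit") <- fit
    out
}

#' Log-rank (Mantel-Cox) test between two groups
#'
#' Observed-minus-expected events accumulated over the pooled event times
#' with the hypergeometric variance; 1 degree of freedom. Symmetric in the
#' group labels.
#'
#' @param time follow-up times
#' @param event 1 = death, 0 = censored
#' @param group two-level grouping
#' @return list(statistic, p.value, n, obs, exp)
#' @export
logrankTest <- function(time, event, group) {
    group <- factor(group)
    if (nlevels(group) != 2L) stop("need exactly two groups")
    if (sum(event) == 0) stop("no events in either group: test undefined")
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    stat <- sd$chisq
    list(statistic = unname(stat),
         p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
         n = as.vector(sd$n), obs = sd$obs, exp = sd$exp)
}
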