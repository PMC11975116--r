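#' Run the VNTR coverage and genotyping QC pipeline end-to-end
#'
#' Orchestrates every stage on a synthetic cohort: simulate (reference,
#' individuals, reads), curate the catalog, compute GC content and
#' STR-like motif scores, count spanning/reliable reads, classify
#' coverage, call genotypes, compare genotypes against an independent
#' whole-genome read set of the same individuals (consistency), evaluate
#' Mendelian consistency over trios, and tabulate the heterozygous
#' miscall probability. All stage tables are written as TSV, the summary
#' as \code{report.json}, and the resolved configuration as
#' \code{config.json}; every report number is recomputable from the
#' stage TSVs. Reruns with the same configuration reproduce the outputs
#' byte for byte.
#'
#' @param params A \code{\link{SimulationParams}} describing the cohort.
#' @param outDir Output directory (created; existing \code{report.json}
#'   is not silently overwritten unless \code{overwrite}).
#' @param wellThreshold,highThreshold,projectionCap Coverage tiers, see
#'   \code{\link{classifyCoverage}}.
#' @param gcCut GC fraction splitting the coverage quadrants.
#' @param strlikeCutoff STR-like score cutoff for consistency analyses.
#' @param minSupport,minFlank,minMatch Genotyping filters.
#' @param tssFlank Promoter window for curation, bp.
#' @param shortReadLengthCut Array-length cutoff used for short-read
#'   style Mendelian restriction, bp.
#' @param alpha Miscall tolerance for the spanning-read threshold.
#' @param compareWgs Simulate a second, unbiased (wgs-mode) read set of
#'   the same individuals and report genotype consistency between the
#'   two read sets.
#' @param overwrite Allow replacing an existing report.
#'
#' @return Invisibly, a list with all stage objects and the
#'   \code{report} list.
#'
#' @examples
#' \donttest{
#' res <- runPipeline(SimulationParams(seed = 7, nLoci = 10,
#'     nSamples = 2, nTrios = 1), tempfile("run"))
#' res$report$tiers
#' }
#' @export
runPipeline <- function(params, outDir,
                        wellThreshold = 15L, highThreshold = 63L,
                        projectionCap = 30L, gcCut = 0.60,
                        strlikeCutoff = 0.8, minSupport = 3L,
                        minFlank = 10L, minMatch = 0.95,
                        tssFlank = 500L, shortReadLengthCut = 150L,
                        alpha = 0.01, compareWgs = TRUE,
                        overwrite = FALSE) {
    stopifnot(methods::is(params, "SimulationParams"))
    if (file.exists(file.path(outDir, "report.json")) && !overwrite)
        stop("report stage: ", file.path(outDir, "report.json"),
             " already exists (set overwrite = TRUE)")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    config <- c(.paramsAsList(params),
        list(wellThreshold = wellThreshold,
             highThreshold = highThreshold,
             projectionCap = projectionCap, gcCut = gcCut,
             strlikeCutoff = strlikeCutoff, minSupport = minSupport,
             minFlank = minFlank, minMatch = minMatch,
             tssFlank = tssFlank,
             shortReadLengthCut = shortReadLengthCut, alpha = alpha))
    jsonlite::write_json(config, file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    tsv <- function(df, name) {
        write.table(df, file.path(outDir, name), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        df
    }
    ## stage: simulate
    cohort <- simulateCohort(params, file.path(outDir, "sim"))
    ## stage: curate
    curated <- curateCatalog(cohort$catalog, cohort$annotation,
                             tssFlank = tssFlank)
    curated$gc_content <- gcContent(curated, cohort$reference)
    writeCatalog(curated, file.path(outDir, "catalog.tsv"))
    ## stage: score-motifs
    scores <- tsv(strlikeScore(motifs(curated), cutoff = strlikeCutoff),
                  "strlike_scores.tsv")
    ## stage: count-spanning
    cov <- countSpanning(cohort$samFiles, curated, cohort$reference,
                         minFlank = minFlank, minMatch = minMatch)
    covTab <- data.frame(locus_id = rep(rownames(cov), ncol(cov)),
        sample_id = rep(colnames(cov), each = nrow(cov)),
        n_spanning = as.vector(spanningCounts(cov)),
        n_reliable = as.vector(reliableCounts(cov)),
        spanning_per_million =
            as.vector(normalizePerMillion(cov)))
    tsv(covTab, "coverage.tsv")
    classification <- tsv(classifyCoverage(cov, wellThreshold,
        highThreshold, projectionCap), "classification.tsv")
    efficiency <- spanningEfficiency(cohort$samFiles[[1]], curated)
    ## stage: genotype
    calls <- tsv(callGenotypes(cov, minSupport), "genotypes.tsv")
    ## stage: concordance (second, unbiased read set)
    concordance <- NULL
    if (compareWgs) {
        p2 <- params
        p2@mode <- "wgs"
        p2@readLengthMedian <- 18000
        p2@depth <- 40
        p2@seed <- params@seed + 1L
        rd2 <- simulateReads(p2, cohort, cohort,
                             file.path(outDir, "sim_wgs"))
        cov2 <- countSpanning(rd2$samFiles, curated, cohort$reference,
                              minFlank = minFlank, minMatch = minMatch)
        calls2 <- tsv(callGenotypes(cov2, minSupport),
                      "genotypes_wgs.tsv")
        concordance <- consistencySummary(calls, calls2,
            catalog = curated, strlikeCutoff = strlikeCutoff)
        tsv(concordance$verdicts, "consistency_verdicts.tsv")
    }
    ## stage: mendelian
    mendel <- NULL
    if (nrow(cohort$ped) > 0) {
        mendel <- mendelianSummary(calls, cohort$ped, catalog = curated,
                                   strlikeCutoff = strlikeCutoff)
        tsv(mendel$per_trio, "mendelian.tsv")
    }
    ## stage: perr
    ptab <- tsv(perrTable(30L), "perr.tsv")
    ## stage: report
    med <- classification$median_spanning
    gc <- curated$gc_content
    quadrants <- c(
        lowgc_covered = sum(gc < gcCut & med >= wellThreshold,
                            na.rm = TRUE),
        lowgc_uncovered = sum(gc < gcCut & med < wellThreshold,
                              na.rm = TRUE),
        highgc_covered = sum(gc >= gcCut & med >= wellThreshold,
                             na.rm = TRUE),
        highgc_uncovered = sum(gc >= gcCut & med < wellThreshold,
                               na.rm = TRUE))
    tierCounts <- table(classification$tier)
    called <- calls[!is.na(calls$allele1), ]
    rcHist <- table(c(called$allele1, called$allele2))
    meanRc <- tapply((called$allele1 + called$allele2) / 2,
                     called$locus_id, mean)
    mlen <- setNames(curated$motif_length, locusIds(curated))
    shared <- intersect(names(meanRc), names(mlen))
    trend <- if (length(shared) >= 3)
        suppressWarnings(stats::cor(mlen[shared], meanRc[shared],
                                    method = "spearman"))
    else NA_real_
    report <- list(
        denominator = sprintf(
            "percentages use the %d curated loci as denominator",
            length(curated)),
        n_candidate_loci = length(cohort$catalog),
        n_curated_loci = length(curated),
        exclusions = as.list(table(
            S4Vectors::metadata(curated)$exclusions$reason)),
        tiers = as.list(tierCounts),
        tier_percent = as.list(round(
            100 * tierCounts / length(curated), 2)),
        quadrants = as.list(quadrants),
        efficiency = efficiency,
        spanning_threshold = minSpanningThreshold(alpha),
        n_str_like = sum(scores$is_str_like),
        repeat_count_histogram = as.list(rcHist),
        motif_length_repeat_count_correlation = trend,
        consistency = if (!is.null(concordance)) list(
            pooled = as.list(concordance$pooled),
            n_comparable = concordance$n_comparable,
            partial_homozygous_side =
                as.list(concordance$partial_homozygous_side)) else NULL,
        mendelian = if (!is.null(mendel)) list(
            pooled = mendel$pooled,
            per_trio = mendel$per_trio) else NULL,
        thresholds_applied = config[c("wellThreshold", "highThreshold",
            "projectionCap", "gcCut", "strlikeCutoff", "minSupport",
            "minFlank", "minMatch", "tssFlank", "alpha")])
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    invisible(list(cohort = cohort, catalog = curated, scores = scores,
                   coverage = cov, classification = classification,
                   calls = calls, concordance = concordance,
                   mendelian = mendel, perr = ptab, report = report,
                   config = config))
}
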