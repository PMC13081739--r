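#' Pipeline configuration
#'
#' Bundles the task design (sequences, rotation offsets, run structure), the
#' simulation parameters and the statistical options for an end-to-end
#' simulated experiment. ROIs are defined by name plus the group-specific
#' amplitude overrides they carry: the default set contains an "M1-like" ROI
#' with the full effect structure (edge boost, compatible-group boost at
#' positions II-IV, incompatible-group boost at position I) and a control
#' ROI with no group-specific amplitudes.
#'
#' @param sim a \code{\link{simulationConfig}}.
#' @param s1 session-1 sequence (integer vector).
#' @param swapPair the two novel keys swapped between sessions.
#' @param compOffset,incompOffset rotation offsets defining the compatible
#'   and incompatible session-2 sequences.
#' @param rois named list; each element is a list of amplitude overrides for
#'   \code{sim} (e.g. \code{list(ampCompNovel = 0)}).
#' @param whitening GLM whitening, "ar1" (default) or "none".
#' @param alpha significance level for gating follow-up tests.
#' @param outdir optional output directory for cached stage artifacts.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(sim = simulationConfig(),
                           s1 = c(4, 7, 3, 8, 6, 2, 5, 1),
                           swapPair = c(2, 3), compOffset = 0L,
                           incompOffset = 3L,
                           rois = list(
                               m1 = list(),
                               control = list(ampCompNovel = 0,
                                              ampIncompFirst = 0)),
                           whitening = "ar1", alpha = 0.05,
                           outdir = NULL, seed = sim$seed) {
    cfg <- list(sim = sim, s1 = s1, swapPair = swapPair,
                compOffset = as.integer(compOffset),
                incompOffset = as.integer(incompOffset), rois = rois,
                whitening = whitening, alpha = alpha, outdir = outdir,
                seed = as.integer(seed))
    class(cfg) <- "pipelineConfig"
    cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the \code{\link{pipelineConfig}} and
#' \code{\link{simulationConfig}} arguments; a commented example ships at
#' \code{system.file("extdata", "demo-config.yaml", package = "schemaRSA")}.
#'
#' @param path YAML file path.
#' @return a \code{pipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    sim <- do.call(simulationConfig, y$sim %||% list())
    args <- y[setdiff(names(y), "sim")]
    do.call(pipelineConfig, c(list(sim = sim), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic sub-seed stream derived from the master seed
.seedStream <- function(seed, n) {
    set.seed(as.integer(seed))
    sample.int(.Machine$integer.max - 1L, n)
}

.applyRoi <- function(sim, overrides) {
    for (nm in names(overrides)) sim[[nm]] <- overrides[[nm]]
    sim
}

#' Simulate and analyse one subject's scanner session
#'
#' Builds the 8 (or \code{nRuns}) run timelines, simulates BOLD data for each
#' ROI from its ground-truth patterns, fits the per-run GLMs and returns one
#' \linkS4class{TPatternSet} per ROI. Run timelines and design matrices are
#' shared across ROIs.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param group "COMP" or "INCOMP".
#' @param subject subject label.
#' @param seed integer seed for this subject.
#' @param level "bold" simulates BOLD runs and fits the per-run GLMs;
#'   "pattern" draws the per-run patterns directly (stable component plus
#'   run perturbation), bypassing the scanner stage. Pattern-level cohorts
#'   isolate the similarity machinery from event-design efficiency effects.
#' @return named list of \linkS4class{TPatternSet} objects, one per ROI.
#' @export
simulateSubject <- function(config, group, subject, seed,
                            level = c("bold", "pattern")) {
    level <- match.arg(level)
    sim <- config$sim
    seqs <- studySequences(config$s1, config$swapPair, config$compOffset,
                           config$incompOffset)
    sq <- if (group == "COMP") seqs$comp else seqs$incomp
    seeds <- .seedStream(seed, sim$nRuns * (1L + length(config$rois)) +
                             length(config$rois))
    si <- 0L
    timelines <- vector("list", sim$nRuns)
    designs <- vector("list", sim$nRuns)
    if (level == "bold") {
        for (r in seq_len(sim$nRuns)) {
            si <- si + 1L
            timelines[[r]] <- buildTimeline(sq, sim$repetitions, sim$rsi,
                                            sim$restCount, sim$restDuration,
                                            runId = r, seed = seeds[si])
            designs[[r]] <- buildDesignMatrix(timelines[[r]], sim$tr)
        }
    } else {
        si <- si + sim$nRuns
    }
    out <- list()
    for (roi in names(config$rois)) {
        roiSim <- .applyRoi(sim, config$rois[[roi]])
        si <- si + 1L
        truth <- makeGroundTruth(roiSim, group, seq = sq, seed = seeds[si])
        if (level == "bold") {
            fits <- vector("list", sim$nRuns)
            for (r in seq_len(sim$nRuns)) {
                si <- si + 1L
                Xc <- designs[[r]]@matrix[, 1:8, drop = FALSE]
                run <- simulateBoldRun(truth, timelines[[r]], roiSim,
                                       seed = seeds[si], regressors = Xc)
                fits[[r]] <- fitGlm(run$data, designs[[r]],
                                    whitening = config$whitening)
            }
            out[[roi]] <- assembleTPatterns(fits, roiName = roi,
                                            subject = subject, group = group)
        } else {
            V <- roiSim$nVoxels
            arr <- array(NA_real_, c(V, 8L, sim$nRuns))
            for (r in seq_len(sim$nRuns)) {
                si <- si + 1L
                set.seed(seeds[si])
                arr[, , r] <- truth$stablePattern +
                    matrix(stats::rnorm(V * 8L), V, 8L) *
                        rep(truth$runSd, each = V)
            }
            out[[roi]] <- new("TPatternSet", t = arr, roiName = roi,
                              subject = subject, group = group,
                              centered = FALSE)
        }
    }
    out
}

#' Simulate a full cohort and compute similarity profiles
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param progress print one line per subject.
#' @param behaviour also simulate the block-level behavioural dataset
#'   (default TRUE).
#' @param level "bold" (full scanner simulation + GLM) or "pattern"
#'   (direct pattern draws); see \code{\link{simulateSubject}}.
#' @return list with \code{similarity} (long data.frame over subjects, ROIs
#'   and positions) and \code{behaviour} (block-level behavioural dataset,
#'   or NULL).
#' @export
simulateCohort <- function(config, progress = FALSE, behaviour = TRUE,
                           level = c("bold", "pattern")) {
    level <- match.arg(level)
    sim <- config$sim
    scheme <- enumerateSplitHalves(sim$nRuns)
    groups <- c("COMP", "INCOMP")
    seeds <- .seedStream(config$seed, 2L * sim$nPerGroup * 2L)
    profiles <- list()
    behav <- list()
    i <- 0L
    for (g in groups) {
        for (s in seq_len(sim$nPerGroup)) {
            i <- i + 1L
            subj <- sprintf("sub-%s-%02d", tolower(g), s)
            tps <- simulateSubject(config, g, subj, seeds[2L * i - 1L],
                                   level = level)
            for (roi in names(tps))
                profiles[[paste(subj, roi)]] <-
                    patternSimilarity(tps[[roi]], scheme)
            if (behaviour)
                behav[[subj]] <- simulateBehavior(sim, g, subj,
                                                  seed = seeds[2L * i])
            if (progress) message("simulated ", subj)
        }
    }
    list(similarity = similarityTable(profiles),
         behaviour = if (behaviour)
             do.call(rbind, c(behav, list(make.row.names = FALSE))))
}

#' Replicate the simulated pipeline and collect a statistic
#'
#' Monte-Carlo harness for calibrating the pipeline's operating
#' characteristics: repeatedly simulates a cohort (BOLD through similarity
#' profiles) under the given configuration and applies a user statistic to
#' each replicate's similarity table. Used for type-I-error calibration of
#' the group-by-position interaction, for the edge-effect detection rate,
#' and for the power of recovering the injected group-specific effects.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param nReplicates number of simulated experiments.
#' @param statistic function(similarityTable) returning a (named) numeric
#'   or logical vector.
#' @param seed master seed for the replicate seed stream.
#' @param progress print one line every 25 replicates.
#' @param level "bold" (full scanner simulation + GLM) or "pattern"
#'   (direct pattern draws); see \code{\link{simulateSubject}}.
#' @return matrix with one row per replicate.
#' @export
replicatePipeline <- function(config, nReplicates, statistic,
                              seed = config$seed, progress = FALSE,
                              level = c("bold", "pattern")) {
    level <- match.arg(level)
    seeds <- .seedStream(seed, nReplicates)
    out <- vector("list", nReplicates)
    for (i in seq_len(nReplicates)) {
        cfg <- config
        cfg$seed <- seeds[i]
        sim <- simulateCohort(cfg, behaviour = FALSE, level = level)
        out[[i]] <- statistic(sim$similarity)
        if (progress && i %% 25L == 0L)
            message("replicate ", i, "/", nReplicates)
    }
    do.call(rbind, out)
}

#' Group-level statistical battery on a similarity table
#'
#' Per ROI: the 2 (group) x 8 (ordinal position) mixed ANOVA with sphericity
#' correction; Benjamini-Hochberg FDR across ROIs applied per effect column;
#' where the FDR-corrected interaction is significant, follow-up Levene-gated
#' independent t-tests per ordinal position with FDR over the eight
#' positions; and the edge-effect contrast (positions I and VIII vs II-VII)
#' tested with a paired t-test across subjects.
#'
#' @param simTable similarity table as returned by
#'   \code{\link{similarityTable}}.
#' @param alpha significance level for gating follow-ups (default 0.05).
#' @return list with \code{anovas} (per-ROI data.frame including
#'   FDR-corrected p per effect), \code{followUps} (per significant ROI, the
#'   8 per-position t-tests with FDR), \code{edge} (per-ROI edge contrast
#'   mean and paired t-test).
#' @export
roiBattery <- function(simTable, alpha = 0.05) {
    rois <- unique(simTable$roi)
    anovas <- list(); wide <- list()
    for (roi in rois) {
        d <- simTable[simTable$roi == roi, ]
        W <- stats::reshape(d[, c("subject", "group", "ordinal_position", "z")],
                            idvar = c("subject", "group"),
                            timevar = "ordinal_position", direction = "wide")
        Y <- as.matrix(W[, -(1:2), drop = FALSE])
        Y <- Y[, order(as.integer(sub(".*\\.", "", colnames(Y)))), drop = FALSE]
        wide[[roi]] <- list(Y = Y, group = W$group)
        a <- mixedAnova(Y, W$group)
        a$roi <- roi
        anovas[[roi]] <- a
    }
    tab <- do.call(rbind, anovas)
    # FDR across ROIs, separately per effect column (as in a multi-ROI table)
    tab$pFdrRoi <- NA_real_
    for (eff in unique(tab$effect)) {
        idx <- tab$effect == eff
        tab$pFdrRoi[idx] <- bhFdr(tab$pCorr[idx])$pAdjusted
    }
    followUps <- list()
    for (roi in rois) {
        sig <- tab$pFdrRoi[tab$roi == roi & tab$effect == "group:within"] < alpha
        if (!isTRUE(sig)) next
        Y <- wide[[roi]]$Y; grp <- wide[[roi]]$group
        tests <- lapply(1:8, function(c)
            independentT(Y[grp == "COMP", c], Y[grp == "INCOMP", c]))
        fu <- data.frame(ordinal_position = 1:8,
                         t = vapply(tests, `[[`, numeric(1), "t"),
                         df = vapply(tests, `[[`, numeric(1), "df"),
                         p = vapply(tests, `[[`, numeric(1), "p"),
                         cohensD = vapply(tests, `[[`, numeric(1), "cohensD"),
                         variant = vapply(tests, `[[`, character(1), "variant"))
        corr <- bhFdr(fu$p)
        fu$pFdr <- corr$pAdjusted
        fu$significant <- corr$rejected
        followUps[[roi]] <- fu
    }
    edge <- lapply(rois, function(roi) {
        Y <- wide[[roi]]$Y
        hi <- rowMeans(Y[, c(1L, 8L)]); lo <- rowMeans(Y[, 2:7])
        tt <- pairedT(hi, lo)
        data.frame(roi = roi, contrast = mean(hi - lo), t = tt$t,
                   df = tt$df, p = tt$p)
    })
    list(anovas = tab, followUps = followUps,
         edge = do.call(rbind, edge))
}

#' Run the full simulated pipeline
#'
#' Orchestrates design construction, cohort simulation (BOLD + behaviour),
#' per-run GLMs, split-half similarity, and the group-level statistical
#' battery. Deterministic given the seed. When \code{outdir} is set, the
#' similarity and behaviour tables are cached there keyed by an md5 hash of
#' the configuration, and a re-run with the same configuration reuses them
#' (the statistics are a pure function of those tables, so the regenerated
#' report is identical).
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param progress print progress messages.
#' @return list of class \code{pipelineReport} with elements
#'   \code{compatibility} (per-group overlap reports),
#'   \code{battery} (see \code{\link{roiBattery}}),
#'   \code{behaviouralAnovas} (per task section, on mean RT),
#'   \code{similarity}, \code{behaviour} (the stage tables), and
#'   \code{provenance} (config hash, seed).
#' @export
runPipeline <- function(config, progress = FALSE) {
    seqs <- studySequences(config$s1, config$swapPair, config$compOffset,
                           config$incompOffset)
    hash <- configHash(config)
    simPath <- behavPath <- NULL
    cohort <- NULL
    if (!is.null(config$outdir)) {
        dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
        simPath <- file.path(config$outdir,
                             paste0("similarity-", hash, ".tsv"))
        behavPath <- file.path(config$outdir,
                               paste0("behaviour-", hash, ".tsv"))
        if (file.exists(simPath) && file.exists(behavPath)) {
            if (progress) message("reusing cached stage tables (", hash, ")")
            cohort <- list(
                similarity = utils::read.table(simPath, sep = "\t",
                                               header = TRUE),
                behaviour = utils::read.table(behavPath, sep = "\t",
                                              header = TRUE))
        }
    }
    if (is.null(cohort)) {
        cohort <- simulateCohort(config, progress = progress)
        if (!is.null(simPath)) {
            writeSimilarityTable(cohort$similarity, simPath)
            utils::write.table(cohort$behaviour, behavPath, sep = "\t",
                               quote = FALSE, row.names = FALSE)
        }
    }
    battery <- roiBattery(cohort$similarity, alpha = config$alpha)
    sections <- c("pretest", "mri", "posttest")
    behavAnovas <- lapply(sections, function(s)
        behaviouralAnova(cohort$behaviour, s, "mean_rt"))
    names(behavAnovas) <- sections
    report <- list(compatibility = list(comp = seqs$compReport,
                                        incomp = seqs$incompReport),
                   battery = battery,
                   behaviouralAnovas = behavAnovas,
                   similarity = cohort$similarity,
                   behaviour = cohort$behaviour,
                   provenance = list(configHash = hash, seed = config$seed))
    class(report) <- "pipelineReport"
    report
}

# md5 hash of the serialized configuration (via a temporary file since
# tools::md5sum hashes files)
configHash <- function(config) {
    tf <- tempfile()
    on.exit(unlink(tf))
    saveRDS(config[setdiff(names(config), "outdir")], tf)
    unname(tools::md5sum(tf))
}

#' @export
print.pipelineReport <- function(x, ...) {
    cat("schemaRSA pipeline report (seed ", x$provenance$seed, ")\n\n",
        sep = "")
    cat("Schema compatibility:\n")
    show(x$compatibility$comp); show(x$compatibility$incomp)
    cat("\nGroup x ordinal position ANOVAs (per ROI):\n")
    print(x$battery$anovas[, c("roi", "effect", "df1Corr", "df2Corr", "F",
                               "pCorr", "pFdrRoi", "peta2")],
          row.names = FALSE, digits = 4)
    if (length(x$battery$followUps) > 0L) {
        cat("\nFollow-up per-position group comparisons:\n")
        for (roi in names(x$battery$followUps)) {
            cat(" ROI:", roi, "\n")
            print(x$battery$followUps[[roi]], row.names = FALSE, digits = 4)
        }
    }
    cat("\nEdge-effect contrasts:\n")
    print(x$battery$edge, row.names = FALSE, digits = 4)
    invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Every reported p-value carries a named correction status (uncorrected,
#' sphericity-corrected, FDR). The file reloads loss-free into the same
#' table structure.
#'
#' @param report a \code{pipelineReport}.
#' @param path JSON output path.
#' @export
writeReport <- function(report, path) {
    out <- list(
        compatibility = list(
            comp = list(overlap_fraction =
                            report$compatibility$comp@overlapFraction,
                        preserved_pairings =
                            report$compatibility$comp@preservedPairings,
                        matched_positions =
                            report$compatibility$comp@matchedPositions),
            incomp = list(overlap_fraction =
                              report$compatibility$incomp@overlapFraction,
                          preserved_pairings =
                              report$compatibility$incomp@preservedPairings,
                          matched_positions =
                              report$compatibility$incomp@matchedPositions)),
        anovas = report$battery$anovas,
        follow_ups = report$battery$followUps,
        edge = report$battery$edge,
        behavioural_anovas = report$behaviouralAnovas,
        p_value_corrections = list(
            pCorr = "sphericity-corrected (GG for eps <= 0.75, HF above)",
            pFdrRoi = "Benjamini-Hochberg across ROIs, per effect",
            pFdr = "Benjamini-Hochberg across the 8 ordinal positions",
            p = "uncorrected"),
        provenance = report$provenance)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    invisible(path)
}

#' Generate the small hand-checkable fixtures used by the unit tests
#'
#' \describe{
#'   \item{toy-glm}{a 12-timepoint, 2-regressor design with hand-specified
#'     values and one voxel, written as TSVs.}
#'   \item{toy-rsa}{a 2-run x 3-voxel x 8-condition t-value table whose
#'     split-half correlations can be verified by hand.}
#'   \item{cohort}{a miniature simulated cohort (4 per group) with manifest.}
#' }
#'
#' @param kind "toy-glm", "toy-rsa" or "cohort".
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return character vector of the files written.
#' @export
generateFixtures <- function(kind = c("toy-glm", "toy-rsa", "cohort"),
                             dir = tempfile("fixtures"), seed = 1L) {
    kind <- match.arg(kind)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    set.seed(as.integer(seed))
    files <- character(0)
    if (kind == "toy-glm") {
        X <- cbind(x1 = c(0, 1, 2, 3, 2, 1, 0, 0, 1, 2, 1, 0),
                   x2 = rep(1, 12))
        y <- c(0.5, 2.1, 4.2, 6.1, 4.3, 2.2, 0.1, -0.2, 2.0, 4.1, 2.3, 0.4)
        f1 <- file.path(dir, "toy-glm-design.tsv")
        f2 <- file.path(dir, "toy-glm-data.tsv")
        utils::write.table(X, f1, sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(data.frame(y = y), f2, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <- c(f1, f2)
    } else if (kind == "toy-rsa") {
        arr <- array(round(stats::rnorm(3 * 8 * 2), 2), c(3, 8, 2))
        long <- data.frame(voxel = rep(1:3, 16),
                           condition = rep(rep(1:8, each = 3), 2),
                           run = rep(1:2, each = 24),
                           t = as.vector(arr))
        f1 <- file.path(dir, "toy-rsa.tsv")
        utils::write.table(long, f1, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <- f1
    } else {
        cfg <- pipelineConfig(sim = simulationConfig(nPerGroup = 4L,
                                                     nVoxels = 12L,
                                                     seed = seed),
                              rois = list(m1 = list()), seed = seed)
        seeds <- .seedStream(seed, 8L)
        i <- 0L
        for (g in c("COMP", "INCOMP")) {
            for (s in 1:4) {
                i <- i + 1L
                subj <- sprintf("sub-%s-%02d", tolower(g), s)
                tps <- simulateSubject(cfg, g, subj, seeds[i])
                f <- file.path(dir, paste0(subj, "-tpatterns.tsv"))
                writeTPatterns(tps$m1, f, seed = seeds[i])
                files <- c(files, f, paste0(f, ".json"))
            }
        }
        manifest <- file.path(dir, "manifest.json")
        jsonlite::write_json(list(kind = kind, seed = seed,
                                  files = basename(files)),
                             manifest, auto_unbox = TRUE)
        files <- c(files, manifest)
    }
    files
}
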