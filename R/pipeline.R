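#' Read a combined two-species transcript FASTA
#'
#' Sequence names carry the species prefix (\code{hs|} / \code{mm|}).
#' Gene ids come from an optional annotation TSV (columns tx, gene, species);
#' without one, the gene id is the transcript id with a trailing
#' \code{.t<n>} variant suffix removed.
#'
#' @param fastaPath Path to the FASTA file.
#' @param annoPath Optional transcript annotation TSV.
#' @return A \linkS4class{TranscriptSet}.
#' @export
readTranscriptSet <- function(fastaPath, annoPath = NULL) {
    if (!file.exists(fastaPath)) stop("FASTA not found: ", fastaPath)
    seqs <- Biostrings::readDNAStringSet(fastaPath)
    nm <- sub("\\s.*$", "", names(seqs))
    species <- ifelse(startsWith(nm, "hs|"), "human",
                      ifelse(startsWith(nm, "mm|"), "mouse", NA))
    if (anyNA(species))
        stop("FASTA names must be prefixed with 'hs|' or 'mm|'")
    tx <- sub("^(hs|mm)\\|", "", nm)
    names(seqs) <- tx
    if (!is.null(annoPath)) {
        anno <- read.delim(annoPath, stringsAsFactors = FALSE)
        if (!all(c("tx", "gene") %in% names(anno)))
            stop("annotation must have 'tx' and 'gene' columns")
        gene <- anno$gene[match(tx, anno$tx)]
        if (anyNA(gene)) stop("annotation missing transcripts")
    } else {
        gene <- sub("\\.t[0-9]+$", "", tx)
    }
    new("TranscriptSet", seqs = seqs, txGene = gene, txSpecies = species)
}

#' Write positional counts as sparse TSV
#'
#' One row per gene and position with any signal: gene, j (distance from the
#' poly-A tail), c (coverage), cprime (read starts).
#'
#' @param counts A \linkS4class{PairCounts}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(counts, path) {
    rows <- lapply(geneIds(counts), function(g) {
        cv <- coverageCounts(counts, g)
        st <- startCounts(counts, g)
        j <- which(cv > 0L | st > 0L)
        if (!length(j)) return(NULL)
        data.frame(gene = g, j = j, c = cv[j], cprime = st[j],
                   stringsAsFactors = FALSE)
    })
    write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read positional counts written by \code{\link{writeCounts}}
#'
#' @param path Counts TSV path.
#' @param ts The \linkS4class{TranscriptSet} the counts were computed on.
#' @param tallies Optional named numeric tallies (restored as zeros when
#'   absent).
#' @return A \linkS4class{PairCounts}.
#' @export
readCounts <- function(path, ts, tallies = NULL) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    reps <- repTranscripts(ts)
    lens <- setNames(Biostrings::width(ts@seqs), names(ts@seqs))
    genes <- names(reps)
    cov <- lapply(genes, function(g) integer(lens[[reps[[g]]]]))
    sta <- lapply(genes, function(g) integer(lens[[reps[[g]]]]))
    names(cov) <- names(sta) <- genes
    for (g in intersect(unique(tab$gene), genes)) {
        sub <- tab[tab$gene == g, , drop = FALSE]
        cov[[g]][sub$j] <- as.integer(sub$c)
        sta[[g]][sub$j] <- as.integer(sub$cprime)
    }
    if (is.null(tallies))
        tallies <- c(total = sum(vapply(sta, sum, numeric(1))),
                     assignedHuman = NA_real_, assignedMouse = NA_real_,
                     excludedCrossSpecies = 0, excludedMultiGene = 0,
                     excludedUnmapped = 0, dropped = 0)
    gspecies <- ts@txSpecies[match(reps, names(ts@seqs))]
    new("PairCounts", gene = genes, species = unname(gspecies), cov = cov,
        starts = sta, tallies = tallies)
}

# plain key=value config file; '#' comments, blank lines ignored
.readRunConfig <- function(path) {
    ln <- readLines(path, warn = FALSE)
    ln <- trimws(sub("#.*$", "", ln))
    ln <- ln[nzchar(ln)]
    kv <- strsplit(ln, "=", fixed = TRUE)
    bad <- lengths(kv) < 2L
    if (any(bad)) stop("malformed config line: ", ln[bad][1])
    vals <- lapply(kv, function(x) trimws(paste(x[-1], collapse = "=")))
    names(vals) <- trimws(vapply(kv, `[[`, character(1), 1L))
    lapply(vals, function(v) {
        n <- suppressWarnings(as.numeric(v))
        if (!is.na(n)) n else v
    })
}

.cfgDefaults <- list(
    out = "xenoLR_run", seed = 1, zMinLow = 10, zMinHigh = 50,
    mdX = 0.75, mdY = 0.75, mdZ = 50, meanSignalMin = 10,
    maxIter = 50, tol = 1e-6, percentile = 0.95, target = 3e5,
    mappabilityK = 50, mappabilityMismatch = 1, qMethod = "storey"
)

#' Run a pipeline stage
#'
#' Chains the analysis stages over file-based inputs and outputs. Config is
#' a named list or the path of a plain key=value text file; recognised keys
#' are the input paths (\code{fasta}, \code{anno}, \code{sam} or
#' \code{placements}, \code{db}, \code{homolog_map}, \code{go_table}), the
#' output directory \code{out}, \code{seed}, and the thresholds/model
#' options (defaults are the analysis defaults: zone boundary 0.5, strong
#' signal 10/50, mutual dependency 0.75/0.75/50, mean-signal filter 10).
#' The resolved configuration is written next to the outputs, so every run
#' is self-describing; deterministic stages rerun bit-identically.
#'
#' @param subcommand One of "simulate", "mappability", "assign", "quantify",
#'   "interactome", "enrich", "all".
#' @param config Named list or path to a key=value config file.
#' @return Invisible named list of written artifact paths.
#' @export
xlrRun <- function(subcommand, config = list()) {
    sub <- match.arg(subcommand,
                     c("simulate", "mappability", "assign", "quantify",
                       "interactome", "enrich", "all"))
    if (is.character(config)) config <- .readRunConfig(config)
    cfg <- utils::modifyList(.cfgDefaults, config)
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    pathOf <- function(f) file.path(cfg$out, f)
    need <- function(key) {
        p <- cfg[[key]]
        if (is.null(p)) stop("config key '", key, "' is required for ", sub)
        if (!file.exists(p)) stop("missing input: ", p)
        p
    }
    # resolved-config echo
    writeLines(paste0(names(cfg), " = ",
                      vapply(cfg, function(x) paste(format(x), collapse = " "),
                             character(1))),
               pathOf(paste0("resolved_config_", sub, ".txt")))
    artifacts <- list()

    loadTs <- function() readTranscriptSet(need("fasta"),
                                           cfg$anno %||% NULL)

    if (sub %in% c("simulate", "all")) {
        scfg <- simulationConfig(seed = as.integer(cfg$seed))
        sim <- simulateTranscriptomes(scfg)
        reads <- simulateReads(scfg, sim)
        artifacts$fasta <- writeSimulatedFasta(sim, pathOf("transcripts.fasta"))
        write.table(reads$placements, pathOf("placements.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(reads$truth, pathOf("truth_pairs.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(sim$homologMap, pathOf("homolog_map.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(sim$blocks, pathOf("homolog_blocks.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        artifacts$placements <- pathOf("placements.tsv")
        # demo interaction database and GO table over the simulated human
        # genes, so a simulated sample runs through every stage
        hg <- names(sim$vHuman)
        set.seed(scfg$seed + 7L)
        nd <- min(25L, floor(length(hg) / 2))
        pick <- sample(hg, 2L * nd)
        demoDb <- data.frame(ligand = pick[seq_len(nd)],
                             receptor = pick[nd + seq_len(nd)],
                             source = "simulated", pmid = "",
                             stringsAsFactors = FALSE)
        writeInteractionDB(demoDb, pathOf("lr_db.tsv"))
        demoGo <- data.frame(
            category = paste0("SIM:", rep(sprintf("%02d", 1:5),
                                          length.out = 2L * nd)),
            gene = pick, name = "simulated category",
            stringsAsFactors = FALSE)
        write.table(demoGo, pathOf("go_table.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        artifacts$db <- pathOf("lr_db.tsv")
        artifacts$go_table <- pathOf("go_table.tsv")
        if (sub == "simulate") return(invisible(artifacts))
        cfg$fasta <- artifacts$fasta
        cfg$placements <- artifacts$placements
        cfg$homolog_map <- pathOf("homolog_map.tsv")
        if (is.null(config$db)) cfg$db <- artifacts$db
        if (is.null(config$go_table)) cfg$go_table <- artifacts$go_table
    }

    if (sub %in% c("mappability", "all")) {
        ts <- loadTs()
        tracks <- mappabilityTracks(ts, k = cfg$mappabilityK,
                                    maxMismatch = cfg$mappabilityMismatch)
        artifacts$mappability <-
            writeMappabilityTracks(tracks, pathOf("mappability.tsv"))
        if (sub == "mappability") return(invisible(artifacts))
    }

    if (sub %in% c("assign", "all")) {
        ts <- if (exists("ts", inherits = FALSE)) ts else loadTs()
        pl <- if (!is.null(cfg$placements)) readPlacements(need("placements"))
              else readSamPlacements(need("sam"), ts)
        asg <- assignPairs(pl)
        counts <- accumulateCounts(asg, ts)
        artifacts$counts <- writeCounts(counts, pathOf("counts.tsv"))
        summ <- summarizeSample(counts)
        jsonlite::write_json(c(summ, as.list(tallies(counts))),
                             pathOf("summary.json"), auto_unbox = TRUE,
                             digits = NA)
        artifacts$summary <- pathOf("summary.json")
        if (sub == "assign") return(invisible(artifacts))
    }

    if (sub %in% c("quantify", "all")) {
        ts <- if (exists("ts", inherits = FALSE)) ts else loadTs()
        if (!exists("tracks", inherits = FALSE))
            tracks <- mappabilityTracks(ts, k = cfg$mappabilityK,
                                        maxMismatch = cfg$mappabilityMismatch)
        if (!exists("counts", inherits = FALSE))
            counts <- readCounts(need("counts"), ts)
        model <- fitBiasModel(counts, ts, tracks, tol = cfg$tol,
                              maxIter = as.integer(cfg$maxIter))
        prof <- estimateCopyNumbers(counts, ts, tracks, model,
                                    target = cfg$target,
                                    percentile = cfg$percentile)
        artifacts$expression <-
            writeExpressionProfile(prof, pathOf("expression.tsv"))
        jsonlite::write_json(
            list(alpha = model@alpha, beta = model@beta,
                 iterations = model@iterations,
                 converged = model@converged),
            pathOf("bias_model.json"), auto_unbox = TRUE, digits = NA)
        artifacts$model <- pathOf("bias_model.json")
        if (sub == "quantify") return(invisible(artifacts))
    }

    if (sub %in% c("interactome", "all")) {
        db <- loadInteractionDB(need("db"))
        if (!exists("prof", inherits = FALSE)) {
            etab <- read.delim(need("expression"),
                               stringsAsFactors = FALSE)
        } else etab <- prof@table
        hv <- setNames(etab$norm[etab$species == "human"],
                       etab$gene[etab$species == "human"])
        mvRaw <- setNames(etab$norm[etab$species == "mouse"],
                          etab$gene[etab$species == "mouse"])
        map <- loadHomologMap(need("homolog_map"))
        mv <- suppressWarnings(collapseMouseHomologs(mvRaw, map))
        iprof <- computeInteractionScores(db, hv, mv)
        artifacts$interactome <-
            writeInteractionProfile(iprof, pathOf("interactome.tsv"))
        artifacts$viewer <- writeViewerJson(iprof, pathOf("viewer.json"))
        md <- extractMutuallyDependent(iprof, xMin = cfg$mdX,
                                       yMin = cfg$mdY, zMin = cfg$mdZ)
        write.table(md, pathOf("mutually_dependent.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        artifacts$mutually_dependent <- pathOf("mutually_dependent.tsv")
        if (sub == "interactome") return(invisible(artifacts))
    }

    if (sub %in% c("enrich", "all")) {
        go <- loadGOTable(need("go_table"))
        if (!exists("iprof", inherits = FALSE)) {
            s <- read.delim(need("interactome"), stringsAsFactors = FALSE)
            s$zone <- as.integer(sub("^(CS|SC)", "", s$zone))
            s$defined <- as.logical(s$defined)
            iprof <- new("InteractionProfile", scores = s, nSamples = 1L)
        }
        zoneSets <- list(CS12 = list(d = "CS", z = c(1L, 2L)),
                         CS13 = list(d = "CS", z = c(1L, 3L)),
                         SC12 = list(d = "SC", z = c(1L, 2L)),
                         SC13 = list(d = "SC", z = c(1L, 3L)))
        for (nmz in names(zoneSets)) {
            zs <- zoneSets[[nmz]]
            res <- analyzeGOModules(go, iprof, zoneSet = zs$z,
                                    direction = zs$d,
                                    qMethod = cfg$qMethod)
            res <- rankCategories(res, meanSignalMin = cfg$meanSignalMin)
            f <- pathOf(paste0("go_", nmz, ".tsv"))
            write.table(res, f, sep = "\t", quote = FALSE,
                        row.names = FALSE)
            artifacts[[paste0("go_", nmz)]] <- f
        }
    }
    invisible(artifacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
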