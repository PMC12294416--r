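#' Assemble a pipeline configuration
#'
#' @param fasta Path to the protein FASTA file.
#' @param enzymes Character vector of built-in protease names
#'   (\code{"papain"}, \code{"ficin"}, \code{"bromelain"}) and/or paths to
#'   rule files in the [readProteaseRules()] format.
#' @param db Path to the activity database TSV.
#' @param out Output directory.
#' @param minPeptideLength Minimum peptide length (default 2).
#' @param counting \code{"distinct"} (default) or \code{"occurrence"}.
#' @param scores Optional path to a peptide score TSV.
#' @param scoreThreshold Bioactivity threshold in [0, 1] (default 0.50).
#' @param ambiguity FASTA ambiguity handling, see [readProteinFasta()].
#' @return A validated list of class \code{"PipelineConfig"}.
#' @seealso [runPipeline()], [readPipelineConfig()]
#' @export
pipelineConfig <- function(fasta, enzymes, db, out,
                           minPeptideLength = 2L,
                           counting = c("distinct", "occurrence"),
                           scores = NULL, scoreThreshold = 0.50,
                           ambiguity = c("reject", "mask")) {
  counting <- match.arg(counting)
  ambiguity <- match.arg(ambiguity)
  if (length(enzymes) == 0L) stop("enzyme list must be nonempty")
  if (!file.exists(fasta)) stop("fasta not found: ", fasta)
  if (!file.exists(db)) stop("activity database not found: ", db)
  if (!is.null(scores) && !file.exists(scores))
    stop("score table not found: ", scores)
  if (scoreThreshold < 0 || scoreThreshold > 1)
    stop("scoreThreshold must lie in [0, 1]")
  structure(list(fasta = fasta, enzymes = enzymes, db = db, out = out,
                 minPeptideLength = as.integer(minPeptideLength),
                 counting = counting, scores = scores,
                 scoreThreshold = scoreThreshold, ambiguity = ambiguity),
            class = "PipelineConfig")
}

#' Read a pipeline configuration file
#'
#' Plain-text format: \code{key = value} lines (keys \code{fasta},
#' \code{db}, \code{out}, \code{min_peptide_length}, \code{counting},
#' \code{scores}, \code{score_threshold}, \code{ambiguity}), an
#' \code{[enzymes]} section listing one built-in name or rule-file path per
#' line, and \code{#} comments. Relative paths are resolved against the
#' config file's directory.
#'
#' @param path Config file path.
#' @return A \code{"PipelineConfig"} list (see [pipelineConfig()]).
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  base <- dirname(normalizePath(path))
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  kv <- list()
  enzymes <- character(0)
  inEnz <- FALSE
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      inEnz <- identical(ln, "[enzymes]")
      if (!inEnz) stop("unknown config section: ", ln)
    } else if (inEnz) {
      enzymes <- c(enzymes, ln)
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      kv[[key]] <- trimws(sub("^[^=]*=", "", ln))
    } else {
      stop("cannot parse config line: ", ln)
    }
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p) || grepl("^/", p)) p else file.path(base, p)
  }
  enzymes <- vapply(enzymes, function(e) {
    if (e %in% c("papain", "ficin", "bromelain")) e else resolve(e)
  }, character(1), USE.NAMES = FALSE)
  pipelineConfig(
    fasta = resolve(kv$fasta), enzymes = enzymes, db = resolve(kv$db),
    out = if (is.null(kv$out)) file.path(base, "out") else resolve(kv$out),
    minPeptideLength = if (is.null(kv$min_peptide_length)) 2L
      else as.integer(kv$min_peptide_length),
    counting = if (is.null(kv$counting)) "distinct" else kv$counting,
    scores = resolve(kv$scores),
    scoreThreshold = if (is.null(kv$score_threshold)) 0.50
      else as.numeric(kv$score_threshold),
    ambiguity = if (is.null(kv$ambiguity)) "reject" else kv$ambiguity)
}

#' Run the full mining pipeline
#'
#' Reads proteins, digests each with every enzyme, matches released peptides
#' against the activity database, and writes all result tables into the
#' output directory: \code{fragments.tsv}, one peptide FASTA per enzyme,
#' \code{matches.tsv}, \code{summary.tsv} (long and wide forms),
#' \code{activities_<enzyme>.tsv}, \code{heatmap_long.tsv}, an optional
#' \code{threshold_counts.tsv}, and \code{run_log.txt}. Runs are
#' deterministic: an identical configuration produces byte-identical output
#' files.
#'
#' @param config A \code{"PipelineConfig"} (see [pipelineConfig()]).
#' @return Invisibly, a list with the in-memory results (\code{digests},
#'   \code{matches}, \code{summary}, \code{profiles}, \code{heatmap},
#'   \code{thresholdCounts}) and \code{out}.
#' @seealso [pipelineConfig()], [genPanel()]
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  proteins <- stage("sequence_io",
                    readProteinFasta(config$fasta, ambiguity = config$ambiguity))
  specs <- stage("protease_rules", lapply(config$enzymes, function(e) {
    if (e %in% c("papain", "ficin", "bromelain")) builtinProtease(e)
    else readProteaseRules(e)
  }))
  enzymeNames <- vapply(specs, proteaseName, character(1))
  if (anyDuplicated(enzymeNames))
    stop("[protease_rules] duplicate enzyme name(s): ",
         paste(unique(enzymeNames[duplicated(enzymeNames)]), collapse = ", "))
  db <- stage("bioactivity_db", loadActivityDB(config$db))
  digests <- stage("digestion",
                   digestSet(proteins, specs,
                             minPeptideLength = config$minPeptideLength))
  matches <- stage("fragment_matching", matchAll(digests, db))
  summaryTab <- stage("fragment_matching",
                      buildSummary(digests, matches, counting = config$counting))
  vocab <- activityVocabulary(db)
  profiles <- lapply(enzymeNames, function(e)
    buildActivityProfile(matches, vocab, protease = e))
  names(profiles) <- enzymeNames
  grid <- data.frame(
    protein_id = vapply(digests, function(r) r@proteinId, character(1)),
    enzyme = vapply(digests, function(r) r@protease, character(1)),
    stringsAsFactors = FALSE)
  heat <- stage("fragment_matching",
                buildHeatmapMatrix(matches, vocab, grid = grid))
  thr <- NULL
  if (!is.null(config$scores)) {
    thr <- stage("score_threshold", {
      part <- classifyBioactive(loadScores(config$scores),
                                threshold = config$scoreThreshold)
      perProteinBioactiveCounts(part, digests)
    })
  }
  stage("reporting", .writePipelineOutputs(
    config, proteins, digests, matches, summaryTab, profiles, heat, thr))
  invisible(list(digests = digests, matches = matches, summary = summaryTab,
                 profiles = profiles, heatmap = heat, thresholdCounts = thr,
                 out = config$out))
}

.writePipelineOutputs <- function(config, proteins, digests, matches,
                                  summaryTab, profiles, heat, thr) {
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  frag <- do.call(rbind, lapply(digests, function(r) {
    data.frame(protein_id = r@proteinId, enzyme = r@protease,
               start = r@fragments$start, end = r@fragments$end,
               sequence = r@fragments$sequence, stringsAsFactors = FALSE)
  }))
  .writeTSV(frag, file.path(out, "fragments.tsv"))
  for (e in unique(frag$enzyme)) {
    sub <- digests[vapply(digests, function(r) r@protease == e, logical(1))]
    peps <- unlist(lapply(sub, function(r) {
      if (length(r@peptides) == 0L) return(character(0))
      stats::setNames(r@peptides,
                      sprintf("%s|%s|pep%04d", r@proteinId, e,
                              seq_along(r@peptides)))
    }))
    if (length(peps))
      writeProteinFasta(Biostrings::AAStringSet(peps),
                        file.path(out, paste0("peptides_", e, ".fasta")))
  }
  flat <- matches
  flat$activities <- vapply(matches$activities, paste, character(1),
                            collapse = ";")
  .writeTSV(flat, file.path(out, "matches.tsv"))
  .writeTSV(summaryTab, file.path(out, "summary.tsv"))
  for (e in names(profiles)) {
    prof <- profiles[[e]]
    prof <- rbind(prof, data.frame(
      activity = "bioactive peptides (distinct)",
      count = attr(profiles[[e]], "bioactive_total")))
    .writeTSV(prof, file.path(out, paste0("activities_", e, ".tsv")))
  }
  .writeTSV(heat$long, file.path(out, "heatmap_long.tsv"))
  if (!is.null(thr)) .writeTSV(thr, file.path(out, "threshold_counts.tsv"))
  cfgLines <- c(
    paste0("fasta = ", config$fasta),
    paste0("db = ", config$db),
    paste0("out = ", config$out),
    paste0("min_peptide_length = ", config$minPeptideLength),
    paste0("counting = ", config$counting),
    paste0("scores = ", if (is.null(config$scores)) "" else config$scores),
    paste0("score_threshold = ", format(config$scoreThreshold)),
    paste0("ambiguity = ", config$ambiguity),
    "[enzymes]", config$enzymes)
  cfgPath <- file.path(out, "config.txt")
  writeLines(cfgLines, cfgPath)
  log <- c(
    paste0("PepDigest ", as.character(utils::packageVersion("PepDigest"))),
    paste0("R ", R.version$major, ".", R.version$minor),
    paste0("config_md5 = ", unname(tools::md5sum(cfgPath))),
    paste0("proteins = ", length(proteins)),
    paste0("enzymes = ", length(config$enzymes)),
    paste0("cleavage_sites = ",
           sum(vapply(digests, function(r) length(r@sites), integer(1)))),
    paste0("fragments = ", nrow(frag)),
    paste0("matches = ", nrow(matches)))
  writeLines(log, file.path(out, "run_log.txt"))
  invisible(out)
}
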