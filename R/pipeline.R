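#' Default pipeline configuration
#'
#' Mirrors the standard docking-campaign conventions: 1000 rigid-body
#' models of which the best 20% (i.e. 200 structures) are refined and
#' analyzed, the 10 best by score reported, restraint upper bound 2.0
#' Angstrom and contact cutoff 5.0 Angstrom.
#'
#' @param seed RNG seed recorded with every report.
#' @return a named list; `analyzedModels` is derived as
#'   `rigidBodyModels * keepFraction`.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  cfg <- list(rigidBodyModels = 1000L, keepFraction = 0.2,
              topN = 10L, airBound = 2.0, contactCutoff = 5.0,
              balance = balanceConfig(), wrap = wrapConfig(),
              wrapWarnFraction = 0.5, sasaPoints = 960L,
              computeBsa = TRUE, seed = as.integer(seed))
  cfg$analyzedModels <- as.integer(round(cfg$rigidBodyModels *
                                           cfg$keepFraction))
  stopifnot(cfg$topN >= 1L)
  cfg
}

## tiny FNV-1a hash for reproducible config fingerprints (hex string)
configHash <- function(x) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(x)),
                           collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- ((h + b) * 16777619) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Pre-screen a restraint set for geometric balance
#'
#' Workflow steps 1-2: build two restraints per domain from the candidate
#' interactions (or take explicit pairs), project the restraint residues
#' about the DNA helix axis and assess their balance across the domains.
#' An unbalanced or one-sided set returns status `"back-loop"` - the signal
#' to choose another interaction pair before spending a docking run.
#'
#' @param complex [ZFStructure-class] holding the protein positioned
#'   relative to the DNA (bound pose or superimposed homology model) and
#'   the DNA chain the axis is fitted on.
#' @param interactions candidate table (`domain`, `proteinRes`, `dnaBase`).
#' @param domains list of [ZincFingerDomain-class]; annotated from the
#'   protein chain when NULL.
#' @param mode `"two-per-domain"` (default) or `"explicit"` (use the table
#'   as-is).
#' @param tblPath if non-NULL and the set is balanced, write the restraint
#'   table here.
#' @param config a [defaultPipelineConfig()] list.
#' @return list with `status` (`"ok"` or `"back-loop"`), `set`, `report`
#'   ([BalanceReport-class]), `view`, `tblPath` and `message`.
#' @export
cmdPrescreen <- function(complex, interactions, domains = NULL,
                         mode = c("two-per-domain", "explicit"),
                         tblPath = NULL, config = defaultPipelineConfig()) {
  mode <- match.arg(mode)
  ch <- complexChains(complex)
  protein <- getChain(complex, ch$protein)
  dna <- getChain(complex, ch$dna)
  if (is.null(domains)) domains <- annotateZincFingers(protein)
  set <- if (mode == "two-per-domain")
    selectTwoPerDomain(interactions, domains, bound = config$airBound)
  else buildPairwiseAirs(interactions, bound = config$airBound)
  axis <- fitHelixAxis(dna)
  view <- projectAIRSet(set, complex, axis)
  report <- assessDistribution(set, view, config$balance)
  if (!isBalanced(report)) {
    bad <- unique(projectionPoints(view)$domain[
      projectionPoints(view)$resno %in% report@offenders])
    msg <- if (report@oneSided)
      "restraints sit on one side of the DNA"
    else if (length(bad))
      paste("domain(s)", paste(bad, collapse = ", "),
            "carry restraints outside their cluster")
    else "unequal restraint counts across domains"
    return(list(status = "back-loop", set = set, report = report,
                view = view, tblPath = NULL,
                message = paste0("unbalanced restraint set (", msg,
                                 "): choose another interaction pair")))
  }
  if (!is.null(tblPath)) writeTbl(set, tblPath)
  list(status = "ok", set = set, report = report, view = view,
       tblPath = tblPath, message = "restraint set balanced")
}

#' Evaluate an ensemble of docked complex models
#'
#' Workflow steps 3-4: per model the wrap-around classification and the
#' restraint-violation energy; the wrap-around tally over the ensemble;
#' the restraint-energy population table; and the top-N ranking by score.
#' iRMSD and F_nat columns are present only when a reference structure is
#' supplied.  When both the wrap-around fraction and the low-energy
#' population are small the status is `"back-loop"`: go back and choose
#' another restraint pair.
#'
#' @param models named list of complex [ZFStructure-class] objects.
#' @param set the [AIRSet-class] used for the docking.
#' @param reference optional reference complex for F_nat / iRMSD.
#' @param scores optional score data.frame from [parseHaddockScores()]
#'   (matched on `model_id`); models are ranked by restraint energy when
#'   absent.
#' @param config a [defaultPipelineConfig()] list.
#' @return list with `reports` (one row per model), `tally`
#'   (`wrapped`/`total`), `populations`, `top` (ranked data.frame),
#'   `status` and `message`.
#' @export
cmdEvaluate <- function(models, set, reference = NULL, scores = NULL,
                        config = defaultPipelineConfig()) {
  if (!length(models)) stop("no models to evaluate")
  if (is.null(names(models)) || any(!nzchar(names(models))))
    names(models) <- sprintf("model_%d", seq_along(models))
  rows <- lapply(names(models), function(id) {
    m <- models[[id]]
    wrap <- classifyWrapAround(m, config = config$wrap)
    ea <- airEnergy(set, m)
    row <- data.frame(model_id = id, wrap_around = wrap$wrapAround,
                      coverage = wrap$coverage, e_air = ea$energy,
                      n_violations = sum(ea$violations$delta > 0),
                      stringsAsFactors = FALSE)
    if (config$computeBsa)
      row$bsa <- bsa(m, nPoints = config$sasaPoints)
    if (!is.null(reference)) {
      row$fnat <- fnat(m, reference, cutoff = config$contactCutoff)
      row$irmsd <- irmsd(m, reference)
    }
    row
  })
  reports <- do.call(rbind, rows)
  eAir <- stats::setNames(reports$e_air, reports$model_id)
  if (is.null(scores))
    scores <- data.frame(model_id = reports$model_id,
                         haddock_score = reports$e_air,
                         stringsAsFactors = FALSE)
  ranked <- rescoreAndRank(scores, n = config$topN)
  pops <- populationTable(scores, eAir)
  reports$rank <- NA_integer_
  hit <- match(ranked$model_id, reports$model_id)
  reports$rank[hit] <- ranked$rank
  wrapped <- sum(reports$wrap_around)
  lowPop <- pops$populations$n[1] / nrow(reports)
  backLoop <- wrapped / nrow(reports) < config$wrapWarnFraction &&
    lowPop < config$wrapWarnFraction
  list(reports = reports,
       tally = c(wrapped = wrapped, total = nrow(reports)),
       populations = pops, top = ranked,
       status = if (backLoop) "back-loop" else "ok",
       message = if (backLoop)
         paste0("few wrap-around models (", wrapped, "/", nrow(reports),
                ") and a small low-energy population: go back to the ",
                "first step and choose another restraint pair")
       else sprintf("%d/%d models wrap around the DNA", wrapped,
                    nrow(reports)))
}

#' Summarise an evaluation as text and JSON
#'
#' @param evaluation output of [cmdEvaluate()].
#' @param config the pipeline configuration used.
#' @param jsonPath optional path for a JSON summary.
#' @return character vector of summary lines, invisibly; the same content
#'   is written to `jsonPath` when given.
#' @export
cmdReport <- function(evaluation, config = defaultPipelineConfig(),
                      jsonPath = NULL) {
  need <- c("reports", "tally", "top", "status")
  if (!all(need %in% names(evaluation)))
    stop("not an evaluation result (missing: ",
         paste(setdiff(need, names(evaluation)), collapse = ", "), ")")
  top <- evaluation$top
  lines <- c(
    sprintf("zfAIR evaluation | config %s | seed %d", configHash(config),
            config$seed),
    sprintf("models analyzed: %d", evaluation$tally[["total"]]),
    sprintf("wrap-around tally: %d/%d", evaluation$tally[["wrapped"]],
            evaluation$tally[["total"]]),
    sprintf("restraint-energy populations: %d",
            nrow(evaluation$populations$populations)),
    sprintf("status: %s", evaluation$status),
    "top models by score:",
    sprintf("  %2d. %s (score %.2f)", top$rank, top$model_id, top$score))
  if (!is.null(jsonPath)) {
    payload <- list(config_hash = configHash(config), seed = config$seed,
                    tally = as.list(evaluation$tally),
                    status = evaluation$status,
                    top = top[, c("rank", "model_id", "score")],
                    populations = evaluation$populations$populations)
    jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(lines)
}
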