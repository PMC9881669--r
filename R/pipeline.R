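## Orchestration: retrieval -> filters -> scorers -> ranking for batches of
## query spectra, plus hierarchical text / HTML / TSV reports.

#' Annotate a batch of query spectra against compound stores
#'
#' For each query: the neutral mass is derived from the precursor m/z and
#' adduct, candidates are retrieved from the union of the stores within the
#' mass window (deduplicated by InChI across stores, first-listed store
#' wins), the optional formula / element / metabolite-likeness filters are
#' applied, the enabled scorers are run, and candidates are ranked by
#' TotalScore (the product of the enabled scorers' values).
#'
#' @param spectra List of \linkS4class{MergedSpectrum} (or a single one).
#' @param stores A \linkS4class{CompoundStore}, store path, or list of
#'   either; all must share a fingerprint layout when the finger scorer is
#'   enabled.
#' @param scorers Character subset of \code{c("frag", "finger")}.
#' @param fingerModels A \linkS4class{FingerModelSet}; required when
#'   \code{"finger"} is enabled. A layout mismatch with any store aborts
#'   the job.
#' @param tol,mode Retrieval mass window (see [queryByMass()]); default
#'   20 ppm.
#' @param knownFormula \code{NULL}, a single formula applied to every
#'   query, or a vector/list with one entry (or \code{NA}) per query.
#' @param allowedElements \code{NULL}, a character vector of element
#'   symbols applied to every query, or a list with one entry (or
#'   \code{NULL}) per query.
#' @param metaboliteClassifier Optional classifier from
#'   [trainMetaboliteClassifier()]; the metabolite-likeness filter is
#'   applied only when this is supplied and \code{metaboliteFilter} is
#'   \code{TRUE} (off by default).
#' @param metaboliteFilter,metaboliteThreshold Enable flag (default
#'   \code{FALSE}) and probability cutoff (default 0.5).
#' @param topN Candidates reported per query (default 20).
#' @param matchPpm,matchDa,hCorrection Fragment match tolerance and
#'   hydrogen-correction flag (see [fragScore()]).
#' @param workers Parallel workers over queries (forked; results are
#'   identical to serial execution).
#' @param verbose Emit one log line per query.
#' @return List of per-query results (class \code{annotationResult}), each
#'   with \code{query_id}, \code{precursor_mz}, \code{adduct},
#'   \code{counts} (candidate counts along the filter chain) and
#'   \code{candidates} (ranked data frame with per-scorer scores,
#'   \code{total_score}, \code{rank}, \code{relative_score},
#'   \code{matched_peaks}).
#' @export
annotate <- function(spectra, stores, scorers = c("frag", "finger"),
                     fingerModels = NULL, tol = 20,
                     mode = c("ppm", "da"), knownFormula = NULL,
                     allowedElements = NULL, metaboliteClassifier = NULL,
                     metaboliteFilter = FALSE, metaboliteThreshold = 0.5,
                     topN = 20L, matchPpm = 20, matchDa = 0.005,
                     hCorrection = TRUE, workers = 1L, verbose = FALSE) {
  mode <- match.arg(mode)
  if (methods::is(spectra, "MergedSpectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1L, topN >= 1L)
  scorers <- match.arg(scorers, c("frag", "finger"), several.ok = TRUE)
  if (!is.list(stores) || methods::is(stores, "CompoundStore"))
    stores <- list(stores)
  stores <- lapply(stores, function(s)
    if (methods::is(s, "CompoundStore")) s else openStore(s))
  if ("finger" %in% scorers) {
    if (is.null(fingerModels))
      stop("the finger scorer needs fingerModels")
    for (s in stores) {
      lid <- s@manifest$layout_id
      if (nzchar(fingerModels@layoutId) &&
          !identical(lid, fingerModels@layoutId))
        stop("layout mismatch: store '", s@path, "' uses layout '", lid,
             "', finger models were trained for '",
             fingerModels@layoutId, "'")
    }
  }
  formulaFor <- .perQuery(knownFormula, length(spectra), "knownFormula")
  elementsFor <- .perQuery(allowedElements, length(spectra),
                           "allowedElements", atomicOk = FALSE)
  one <- function(qi) {
    sp <- spectra[[qi]]
    t0 <- proc.time()[["elapsed"]]
    neutral <- neutralMassFromPrecursor(sp@precursorMz, sp@adduct)
    cands <- NULL
    for (si in seq_along(stores)) {
      h <- queryByMass(stores[[si]], neutral, tol = tol, mode = mode)
      h$store <- rep(si, nrow(h))
      cands <- if (is.null(cands)) h else rbind(cands, h)
    }
    cands <- cands[order(cands$store), , drop = FALSE]
    cands <- cands[!duplicated(cands$inchi), , drop = FALSE]
    counts <- c(retrieved = nrow(cands))
    fq <- formulaFor(qi)
    if (!is.null(fq) && !is.na(fq)) {
      cands <- filterFormula(cands, fq)
      counts <- c(counts, formula = nrow(cands))
    }
    eq <- elementsFor(qi)
    if (!is.null(eq)) {
      cands <- filterElements(cands, eq)
      counts <- c(counts, elements = nrow(cands))
    }
    if (isTRUE(metaboliteFilter) && !is.null(metaboliteClassifier)) {
      cands <- filterMetaboliteLikeness(cands, metaboliteClassifier,
                                        threshold = metaboliteThreshold)
      counts <- c(counts, metabolite = nrow(cands))
    }
    scoreCols <- list()
    matched <- list()
    if (nrow(cands)) {
      if ("frag" %in% scorers) {
        fs <- lapply(cands$frag_pattern, function(p)
          fragScore(sp, p, ppm = matchPpm, da = matchDa,
                    hCorrection = hCorrection))
        scoreCols$frag <- vapply(fs, `[[`, numeric(1), "score")
        matched <- lapply(fs, `[[`, "matched_peaks")
      }
      if ("finger" %in% scorers) {
        pred <- predictFingerprintBits(fingerModels, sp)
        scoreCols$finger <- vapply(cands$fingerprint, function(fp)
          fingerScore(pred, fp, fingerModels), numeric(1))
      }
    }
    ranked <- combineAndRank(cands, scoreCols)
    if ("frag" %in% scorers && nrow(ranked)) {
      ## matched peaks follow the candidates through the re-ordering
      key <- match(ranked$inchi, cands$inchi)
      ranked$matched_peaks <- matched[key]
    }
    ranked <- ranked[seq_len(min(topN, nrow(ranked))), , drop = FALSE]
    if (verbose)
      message(sprintf("[%s] %s: %d candidates -> %d reported (%.2fs)",
                      format(Sys.time(), "%H:%M:%S"), sp@id,
                      counts[["retrieved"]], nrow(ranked),
                      proc.time()[["elapsed"]] - t0))
    structure(list(query_id = sp@id, precursor_mz = sp@precursorMz,
                   adduct = sp@adduct, neutral_mass = neutral,
                   counts = counts, candidates = ranked),
              class = "annotationResult")
  }
  if (workers > 1L) {
    res <- parallel::mclapply(seq_along(spectra), one,
                              mc.cores = workers, mc.preschedule = TRUE)
    err <- vapply(res, inherits, logical(1), "try-error")
    if (any(err)) stop("worker failure: ", res[[which(err)[1]]])
    res
  } else {
    lapply(seq_along(spectra), one)
  }
}

## normalize per-query option: NULL / scalar / per-query vector or list
.perQuery <- function(x, n, what, atomicOk = TRUE) {
  if (is.null(x)) return(function(i) NULL)
  if (is.list(x)) {
    if (length(x) != n)
      stop(what, " list must have one entry per query")
    return(function(i) x[[i]])
  }
  if (atomicOk && length(x) == 1L) return(function(i) x)
  if (atomicOk && length(x) == n) return(function(i) x[i])
  if (!atomicOk) return(function(i) x)  # one element set for all queries
  stop(what, " must be NULL, length 1, or one per query")
}

#' @export
print.annotationResult <- function(x, ...) {
  cat("annotationResult ", x$query_id, ": ",
      paste(names(x$counts), x$counts, sep = "=", collapse = " -> "),
      "\n", sep = "")
  if (nrow(x$candidates)) {
    top <- x$candidates[1, ]
    cat(sprintf("  top hit %s (%s) total=%.4f\n", top$inchikey,
                top$formula, top$total_score))
  } else cat("  no candidates\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Reports

#' Write hierarchical text, HTML and summary reports
#'
#' Writes one indented text file per query
#' (\code{<query_id>.txt}: query header, then one block per ranked
#' candidate with identifiers, per-scorer scores and matched peaks), a
#' combined \code{report.html} (one section per query with a sortable
#' candidate table) and \code{summary.tsv} (one row per query: rank-1
#' candidate and scores). Output is byte-stable under re-runs on the same
#' results.
#'
#' @param results List from [annotate()].
#' @param outDir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeReports <- function(results, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  paths <- character(0)
  for (r in results) {
    p <- file.path(outDir, paste0(.safeName(r$query_id), ".txt"))
    writeLines(.textReport(r), p)
    paths <- c(paths, p)
  }
  html <- file.path(outDir, "report.html")
  writeLines(.htmlReport(results), html)
  tsv <- file.path(outDir, "summary.tsv")
  utils::write.table(.summaryTable(results), tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(paths, html, tsv))
}

.safeName <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

.textReport <- function(r) {
  out <- c(
    paste0("query ", r$query_id),
    sprintf("  precursor.mz %.6f", r$precursor_mz),
    paste0("  adduct ", r$adduct),
    sprintf("  neutral.mass %.6f", r$neutral_mass),
    paste0("  candidates ",
           paste(names(r$counts), r$counts, sep = "=", collapse = " -> "))
  )
  cd <- r$candidates
  if (!nrow(cd)) return(c(out, "  no candidates"))
  for (i in seq_len(nrow(cd))) {
    row <- cd[i, ]
    sc <- setdiff(grep("_score$", names(cd), value = TRUE),
                  c("total_score", "relative_score"))
    cols <- c(sc, "total_score", "relative_score")
    scTxt <- paste(sprintf("%s=%.6f", sub("_score$", "", cols),
                           unlist(row[cols])), collapse = " ")
    out <- c(out,
             sprintf("  %d. %s", row$rank, row$inchikey),
             paste0("     ", scTxt),
             sprintf("     formula %s  exact.mass %.6f  delta.mass %+.6f",
                     row$formula, row$exact_mass, row$delta_mass),
             paste0("     source ", row$source_db, ":", row$id))
    if (!is.null(cd$matched_peaks)) {
      mp <- row$matched_peaks[[1]]
      out <- c(out, sprintf("     matched.peaks %d", nrow(mp)))
      if (nrow(mp))
        out <- c(out, sprintf(
          "       mz %.6f -> fragment %.6f (%+dH) intensity %.6f",
          mp$query_mz, mp$fragment_mass, mp$correction, mp$intensity))
    }
  }
  out
}

.esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.htmlReport <- function(results) {
  rows <- function(r) {
    cd <- r$candidates
    if (!nrow(cd)) return("<p>no candidates</p>")
    sc <- setdiff(grep("_score$", names(cd), value = TRUE),
                  c("total_score", "relative_score"))
    head <- paste0("<tr>", paste0("<th>", .esc(c(
      "rank", "inchikey", "formula", sub("_score$", "", sc),
      "total", "relative")), "</th>", collapse = ""), "</tr>")
    body <- vapply(seq_len(nrow(cd)), function(i) {
      row <- cd[i, ]
      cells <- c(row$rank, row$inchikey, row$formula,
                 sprintf("%.6f", unlist(row[sc])),
                 sprintf("%.6f", row$total_score),
                 sprintf("%.4f", row$relative_score))
      paste0("<tr>", paste0("<td>", .esc(as.character(cells)), "</td>",
                            collapse = ""), "</tr>")
    }, character(1))
    paste0("<table class=\"cand\">", head,
           paste(body, collapse = ""), "</table>")
  }
  sections <- vapply(results, function(r) paste0(
    "<section><h2>", .esc(r$query_id), "</h2><p>precursor m/z ",
    sprintf("%.6f", r$precursor_mz), " (", .esc(r$adduct),
    "), candidates: ",
    .esc(paste(names(r$counts), r$counts, sep = "=", collapse = " → ")),
    "</p>", rows(r), "</section>"), character(1))
  c("<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    "<title>annotation report</title>",
    "<style>table.cand{border-collapse:collapse}",
    "table.cand td,table.cand th{border:1px solid #999;padding:2px 6px}",
    "th{cursor:pointer;background:#eee}</style>",
    "<script>",
    "function srt(t,c){var b=t.tBodies.length?t.tBodies[0]:t;",
    "var r=Array.prototype.slice.call(t.rows,1);",
    "r.sort(function(x,y){var a=x.cells[c].innerText,",
    "d=y.cells[c].innerText;var na=parseFloat(a),nd=parseFloat(d);",
    "if(!isNaN(na)&&!isNaN(nd))return nd-na;",
    "return a.localeCompare(d);});",
    "for(var i=0;i<r.length;i++)b.appendChild(r[i]);}",
    "window.onload=function(){var ts=document.querySelectorAll('table.cand');",
    "ts.forEach(function(t){var h=t.rows[0];",
    "for(var c=0;c<h.cells.length;c++){(function(cc){",
    "h.cells[cc].onclick=function(){srt(t,cc);};})(c);}});};",
    "</script></head><body>",
    "<h1>metaboMatch annotation report</h1>",
    sections,
    "</body></html>")
}

.summaryTable <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    cd <- r$candidates
    if (!nrow(cd))
      return(data.frame(query_id = r$query_id, retrieved =
                          r$counts[["retrieved"]], rank1_inchikey = NA,
                        rank1_formula = NA, total_score = NA,
                        stringsAsFactors = FALSE))
    data.frame(query_id = r$query_id, retrieved = r$counts[["retrieved"]],
               rank1_inchikey = cd$inchikey[1],
               rank1_formula = cd$formula[1],
               total_score = cd$total_score[1], stringsAsFactors = FALSE)
  }))
}
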