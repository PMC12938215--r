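#' Run the full attention-audit pipeline
#'
#' Executes the complete audit end to end: phantom dataset generation,
#' patient-wise splitting, classifier training, Grad-CAM activation grids and
#' regions for every test frame, oracle annotation plus simulated noisy
#' raters, majority-rule consensus with oracle adjudication of full
#' disagreements, inter-rater agreement statistics, classification metrics
#' (per class, macro, weighted, and stratified by consensus attention
#' category), and max-intensity-cell frequency maps. All artifacts are
#' written under \code{config$outDir}; the run is fully reproducible from
#' (config, seed). A stage failure aborts with the stage name; artifacts of
#' completed stages are already on disk.
#'
#' @param config A \code{\link{runConfig}}.
#' @return Invisibly, the report list (also serialized as
#'   \code{report.json} and \code{report.html}).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seeds <- list(phantom = deriveSeed(config$seed, "phantom"),
                split = deriveSeed(config$seed, "split"),
                train = deriveSeed(config$seed, "train"),
                raters = deriveSeed(config$seed, "raters"))

  ds <- stage("generate", {
    pargs <- config$phantom
    if (is.null(pargs$seed)) pargs$seed <- seeds$phantom
    pcfg <- do.call(phantomConfig, pargs)
    d <- generateDataset(pcfg)
    writeManifest(d$manifest, file.path(outDir, "manifest.csv"))
    d
  })

  targs <- config$train
  if (is.null(targs$seed)) targs$seed <- seeds$train
  tcfg <- do.call(trainConfig, targs)

  split <- stage("split", splitPatientwise(ds$manifest, tcfg$splitFractions,
                                           seed = seeds$split))

  model <- stage("train", {
    m <- trainModel(ds$frames, split, tcfg)
    saveModel(m, file.path(outDir, "model.json"))
    writeHistory(m, file.path(outDir, "history.csv"))
    m
  })

  expl <- stage("explain", {
    grids <- list(); regions <- list()
    preds <- vector("list", length(split$test))
    for (i in seq_along(split$test)) {
      id <- split$test[i]
      fr <- ds$frames[[id]]
      p <- predictProba(model, fr@image)
      target <- if (isTRUE(config$gradcam$useTrueClass)) fr@station else NULL
      g <- computeCAM(model, fr@image, targetClass = target)
      grids[[id]] <- g
      regions[[id]] <- extractRegion(g, config$gradcam$threshold)
      preds[[i]] <- data.frame(image_id = id, true_station = fr@station,
                               predicted_station = names(which.max(p)),
                               stringsAsFactors = FALSE)
    }
    predictions <- do.call(rbind, preds)
    utils::write.csv(predictions, file.path(outDir, "predictions.csv"),
                     row.names = FALSE)
    writeRegions(grids, regions, file.path(outDir, "regions.json"))
    list(grids = grids, regions = regions, predictions = predictions)
  })

  ann <- stage("annotate", {
    rules <- overlapRules(config$annotation$minFraction,
                          config$annotation$qualityFloor)
    truth <- vapply(split$test, function(id)
      oracleLabel(expl$regions[[id]], ds$frames[[id]], rules), "")
    recs <- withSeed(seeds$raters, {
      out <- list()
      for (r in seq_len(config$annotation$nRaters)) {
        rm <- raterModel(sprintf("r%d", r),
                         flipProbability = config$annotation$flipProbability)
        out[[r]] <- data.frame(image_id = split$test,
                               rater_id = rm$raterId,
                               label = simulateRater(truth, rm),
                               stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    })
    writeAnnotations(recs, file.path(outDir, "annotations.csv"))
    list(truth = truth, records = recs)
  })

  cons <- stage("consensus", {
    cr <- consensus(ann$records)
    pending <- cr$image_id[is.na(cr$final_label)]
    if (length(pending)) {
      adj <- data.frame(image_id = pending,
                        final_label = ann$truth[pending],
                        stringsAsFactors = FALSE)
      cr <- adjudicate(cr, adj)
    }
    writeConsensus(cr, file.path(outDir, "consensus.csv"))
    cr
  })

  agree <- stage("agree", {
    rep <- agreementReport(ann$records)
    writeAgreementReport(rep, file.path(outDir, "agreement.json"))
    rep
  })

  evalRes <- stage("evaluate", {
    am <- aggregateMetrics(expl$predictions$true_station,
                           expl$predictions$predicted_station)
    strat <- stratifyMetrics(expl$predictions, cons)
    utils::write.csv(cbind(data.frame(station = rownames(am$confusion)),
                           as.data.frame(am$confusion)),
                     file.path(outDir, "confusion.csv"), row.names = FALSE)
    list(aggregate = am, stratified = strat)
  })

  freq <- stage("frequency", {
    fq <- maxCellFrequency(unname(expl$regions),
                           vapply(split$test, function(id)
                             ds$frames[[id]]@station, ""))
    rows <- list()
    for (m in c(fq$perStation, list(fq$overall))) {
      cnt <- mapCounts(m)
      for (r in 1:7) for (col in 1:7)
        rows[[length(rows) + 1]] <- data.frame(scope = mapScope(m), row = r,
                                               col = col,
                                               count = cnt[r, col])
    }
    utils::write.csv(do.call(rbind, rows),
                     file.path(outDir, "frequency_maps.csv"),
                     row.names = FALSE)
    renderHeatmaps(fq, file.path(outDir, "heatmaps.png"))
    fq
  })

  report <- buildReport(config, seeds, ds, split, model, expl, ann, cons,
                        agree, evalRes, freq)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  writeHtmlReport(report, file.path(outDir, "report.html"))
  invisible(report)
}

buildReport <- function(config, seeds, ds, split, model, expl, ann, cons,
                        agree, evalRes, freq) {
  am <- evalRes$aggregate
  perClass <- formatMetrics(am$perClass)
  dist <- agreementDistribution(cons)
  strat <- lapply(evalRes$stratified, function(x)
    as.list(c(roundHalfUp(x[c("accuracy", "precision", "sensitivity", "f1")], 1),
              support = unname(x["support"]))))
  list(
    seed = config$seed,
    stage_seeds = seeds,
    dataset = list(n_frames = nrow(ds$manifest),
                   n_patients = length(unique(ds$manifest$patient_id)),
                   stations = as.list(table(ds$manifest$station))),
    split = list(n_train = length(split$train),
                 n_validation = length(split$validation),
                 n_test = length(split$test),
                 patients = split$patients),
    training = list(selected_epoch = model@selectedEpoch,
                    epochs_run = max(model@history$epoch),
                    best_val_loss = min(model@history$loss[
                      model@history$split == "validation"])),
    tables = list(
      per_class = perClass,
      averages = list(
        accuracy = roundHalfUp(am$accuracy, 1),
        macro = as.list(roundHalfUp(am$macro, 1)),
        weighted = as.list(roundHalfUp(am$weighted, 1)),
        n_images = am$nImages),
      confusion_matrix = list(classes = rownames(am$confusion),
                              counts = unname(apply(am$confusion, 1, as.list))),
      agreement = list(
        percent_agreement = roundHalfUp(agree@percentAgreement, 1),
        fleiss = roundHalfUp(agree@fleiss, 3),
        cohen = as.list(roundHalfUp(agree@cohen, 3)),
        interpretations = as.list(agree@interpretations)),
      agreement_distribution = dist,
      stratified = strat),
    attention = list(
      n_degenerate = freq$nDegenerate,
      overall_counts = unname(apply(mapCounts(freq$overall), 1, as.list)))
  )
}

# Minimal static HTML rendering of the report tables.
writeHtmlReport <- function(report, path) {
  esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", as.character(x)))
  tbl <- function(df) {
    paste0("<table border='1'><tr>",
           paste0("<th>", esc(names(df)), "</th>", collapse = ""), "</tr>",
           paste(apply(df, 1, function(r)
             paste0("<tr>", paste0("<td>", esc(r), "</td>", collapse = ""),
                    "</tr>")), collapse = ""),
           "</table>")
  }
  html <- c("<html><head><title>Attention audit report</title></head><body>",
            "<h1>Attention audit report</h1>",
            sprintf("<p>seed %d; %d frames, %d test images</p>",
                    report$seed, report$dataset$n_frames,
                    report$split$n_test),
            "<h2>Per-class metrics</h2>", tbl(report$tables$per_class),
            "<h2>Averages</h2>",
            sprintf("<p>accuracy %.1f%%; macro P/S/F1 %.1f/%.1f/%.1f; weighted %.1f/%.1f/%.1f</p>",
                    report$tables$averages$accuracy,
                    report$tables$averages$macro$precision,
                    report$tables$averages$macro$sensitivity,
                    report$tables$averages$macro$f1,
                    report$tables$averages$weighted$precision,
                    report$tables$averages$weighted$sensitivity,
                    report$tables$averages$weighted$f1),
            "<h2>Agreement</h2>",
            sprintf("<p>percent agreement %.1f%%; Fleiss kappa %.3f (%s)</p>",
                    report$tables$agreement$percent_agreement,
                    report$tables$agreement$fleiss,
                    report$tables$agreement$interpretations$fleiss),
            "<h2>Agreement distribution</h2>",
            tbl(report$tables$agreement_distribution),
            "<h2>Stratified metrics</h2>",
            tbl(do.call(rbind, lapply(names(report$tables$stratified),
                                      function(nm)
              data.frame(category = nm,
                         as.data.frame(report$tables$stratified[[nm]]))))),
            "</body></html>")
  writeLines(html, path)
  invisible(path)
}
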