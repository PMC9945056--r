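open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

find_one <- function(dir, stems) {
  for (s in stems) {
    p <- file.path(dir, s)
    if (file.exists(p)) return(p)
    if (file.exists(paste0(p, ".gz"))) return(paste0(p, ".gz"))
  }
  stop("missing file in '", dir, "': expected one of ",
       paste(stems, collapse = ", "), " (optionally .gz)")
}

#' Read a 10x-style count directory for one slide
#'
#' Expects `matrix.mtx(.gz)` (genes x spots, MatrixMarket), `features.tsv(.gz)`
#' (gene ids in column 1), `barcodes.tsv(.gz)` (spot ids) and a coordinates
#' table with header `spot_id,x,y` (default `coordinates.csv`, CSV or TSV,
#' override via `coords`). Spots missing from the coordinates table are
#' dropped with a warning; if fewer than half the barcodes match, the
#' pairing is considered wrong and an error is raised.
#'
#' @param path Directory with the three matrix files.
#' @param coords Optional path to the coordinates table.
#' @param slide_id Slide identifier (default: directory basename).
#' @return A [slide_data] with sparse counts and coordinates.
#' @export
read_counts_dir <- function(path, coords = NULL, slide_id = basename(path)) {
  if (!dir.exists(path)) stop("directory not found: ", path)
  mtx <- find_one(path, "matrix.mtx")
  feat <- find_one(path, "features.tsv")
  bc <- find_one(path, "barcodes.tsv")
  if (is.null(coords))
    coords <- find_one(path, c("coordinates.csv", "coordinates.tsv"))
  first <- readLines(open_maybe_gz(mtx), n = 1L)
  if (!grepl("^%%MatrixMarket", first))
    stop("malformed MatrixMarket header at line 1 of ", mtx, ": '", first, "'")
  m <- as(Matrix::readMM(open_maybe_gz(mtx)), "CsparseMatrix")
  features <- utils::read.delim(open_maybe_gz(feat), header = FALSE,
                                stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(open_maybe_gz(bc), header = FALSE,
                                stringsAsFactors = FALSE)[[1L]]
  if (nrow(features) != nrow(m) || length(barcodes) != ncol(m))
    stop("matrix is ", nrow(m), " x ", ncol(m), " but features/barcodes have ",
         nrow(features), "/", length(barcodes), " entries")
  rownames(m) <- features[[1L]]
  colnames(m) <- barcodes
  sep <- if (grepl("\\.tsv(\\.gz)?$", coords)) "\t" else ","
  co <- utils::read.table(open_maybe_gz(coords), header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("spot_id", "x", "y") %in% names(co)))
    stop("coordinates table ", coords, " must have columns spot_id, x, y")
  hit <- match(barcodes, co$spot_id)
  matched <- !is.na(hit)
  if (mean(matched) < 0.5)
    stop("only ", sum(matched), "/", length(barcodes),
         " barcodes matched the coordinates table; wrong file pairing?")
  if (!all(matched))
    warning(sum(!matched), " spot(s) without coordinates dropped")
  m <- m[, matched, drop = FALSE]
  spots <- data.frame(spot_id = barcodes[matched],
                      x = co$x[hit[matched]], y = co$y[hit[matched]],
                      stringsAsFactors = FALSE)
  slide_data(slide_id, spots, counts = m)
}

#' Write a slide's counts as a 10x-style directory
#'
#' Inverse of [read_counts_dir]; used by the simulator's count layer and in
#' round-trip tests. Writes uncompressed `matrix.mtx`, `features.tsv`,
#' `barcodes.tsv` and `coordinates.csv`.
#'
#' @param slide A [slide_data] with counts.
#' @param path Output directory (created).
#' @return `path`, invisibly.
#' @export
write_counts_dir <- function(slide, path) {
  stopifnot(inherits(slide, "slide_data"), !is.null(slide$counts))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(as(slide$counts, "generalMatrix"),
                  file.path(path, "matrix.mtx"))
  writeLines(rownames(slide$counts), file.path(path, "features.tsv"))
  writeLines(colnames(slide$counts), file.path(path, "barcodes.tsv"))
  utils::write.csv(slide$spots, file.path(path, "coordinates.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-slide embeddings from CSV
#'
#' Expects header `spot_id,x,y,pc1,...,pcq`; the embedding dimension is
#' inferred from the number of `pc` columns. Non-numeric embedding or
#' coordinate entries are reported with their row number.
#'
#' @param path CSV file.
#' @param slide_id Slide identifier (default: file name without extension).
#' @return A [slide_data] with embeddings and coordinates.
#' @export
read_embeddings_csv <- function(path, slide_id = sub("\\.csv$", "",
                                                     basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("embeddings CSV ", path, " must start with columns spot_id, x, y; ",
         "missing: ", paste(setdiff(need, names(df)), collapse = ", "))
  pccols <- grep("^pc[0-9]+$", names(df), value = TRUE)
  if (!length(pccols)) stop("no pc1..pcq columns found in ", path)
  pccols <- pccols[order(as.integer(sub("^pc", "", pccols)))]
  num <- suppressWarnings(
    vapply(df[c("x", "y", pccols)], as.numeric, numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(NULL, c("x", "y", pccols)))
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1L]
    stop("non-numeric value at data row ", bad, " of ", path)
  }
  spots <- data.frame(spot_id = df$spot_id, x = num[, "x"], y = num[, "y"],
                      stringsAsFactors = FALSE)
  emb <- num[, pccols, drop = FALSE]
  rownames(emb) <- df$spot_id
  slide_data(slide_id, spots, embeddings = emb)
}

emb_df <- function(ds, mat_list, prefix) {
  do.call(rbind, lapply(seq_along(ds$slides), function(t) {
    sl <- ds$slides[[t]]
    m <- mat_list[[t]]
    colnames(m) <- paste0(prefix, seq_len(ncol(m)))
    cbind(data.frame(slide_id = sl$slide_id, spot_id = sl$spots$spot_id,
                     stringsAsFactors = FALSE), as.data.frame(m))
  }))
}

params_to_json_list <- function(fit) {
  p <- fit$params
  list(K = fit$K,
       mu = p$mu,
       sigma = lapply(seq_len(dim(p$sigma)[3L]), function(k) p$sigma[, , k]),
       lambda = p$lambda,
       beta = p$beta,
       loglik = fit$loglik,
       mbic = fit$mbic,
       n_iter = fit$n_iter,
       converged = fit$converged,
       seed = fit$config$seed,
       config = unclass(fit$config),
       slide_ids = fit$slide_ids,
       package_version = as.character(utils::packageVersion("smirf")))
}

#' Re-read fitted model parameters from params.json
#'
#' @param path The `params.json` written by [write_fit_outputs].
#' @return List with `mu`, `sigma` (q x q x K array), `lambda`, `beta`,
#'   plus the scalar metadata.
#' @export
read_params_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- nrow(j$mu)
  q <- ncol(j$mu)
  sigma <- array(0, c(q, q, K))
  if (is.array(j$sigma) && length(dim(j$sigma)) == 3L) {
    for (k in seq_len(K)) sigma[, , k] <- j$sigma[k, , ]
  } else {
    for (k in seq_len(K)) sigma[, , k] <- matrix(unlist(j$sigma[[k]]), q, q,
                                                 byrow = TRUE)
  }
  j$mu <- matrix(as.numeric(j$mu), K, q)
  j$lambda <- matrix(as.numeric(j$lambda), ncol = q)
  j$sigma <- sigma
  j
}

#' Write fitting outputs to a directory
#'
#' Emits `labels.csv` (slide_id, spot_id, x, y, label — the argmax hard
#' assignment, ties to the smaller index), `resp.csv` (soft assignments,
#' rows summing to 1), `corrected_embeddings.csv` (z = v - u), `u.csv`
#' (batch embeddings) and `params.json` (parameters, MBIC table when a
#' multi-K fit is given, config echo and seed). Row order is deterministic:
#' slides in dataset order, spots in file order. Re-running the same
#' configuration byte-reproduces every file.
#'
#' @param fit An `hmrf_fit` or `hmrf_fit_list` (the selected fit is
#'   written).
#' @param ds The dataset that was fitted.
#' @param outdir Output directory (created).
#' @return `outdir`, invisibly.
#' @export
write_fit_outputs <- function(fit, ds, outdir) {
  tab <- NULL
  if (inherits(fit, "hmrf_fit_list")) {
    tab <- fit$mbic_table
    fit <- fit$best
  }
  stopifnot(inherits(fit, "hmrf_fit"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  labels <- split_by_slide(ds, fit$state$labels)
  ldf <- do.call(rbind, lapply(seq_along(ds$slides), function(t) {
    sl <- ds$slides[[t]]
    data.frame(slide_id = sl$slide_id, spot_id = sl$spots$spot_id,
               x = sl$spots$x, y = sl$spots$y, label = labels[[t]],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(ldf, file.path(outdir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(emb_df(ds, split_by_slide(ds, fit$state$resp), "r"),
                   file.path(outdir, "resp.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(emb_df(ds, corrected_embeddings(ds, fit), "z"),
                   file.path(outdir, "corrected_embeddings.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(emb_df(ds, split_by_slide(ds, fit$state$u), "u"),
                   file.path(outdir, "u.csv"), row.names = FALSE,
                   quote = FALSE)
  pj <- params_to_json_list(fit)
  if (!is.null(tab)) pj$mbic_table <- tab
  jsonlite::write_json(pj, file.path(outdir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor")
  invisible(outdir)
}

#' Write a simulated dataset to disk
#'
#' One embeddings CSV per slide in the format [read_embeddings_csv] reads
#' (`spot_id,x,y,pc1..pcq`) plus `truth_labels.csv` with the generative
#' labels and a `sim_config.json` echo. When the simulation carries a count
#' layer, also writes one 10x-style directory per slide.
#'
#' @param sim Result of [simulate_multisample].
#' @param outdir Output directory (created).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ds <- sim$dataset
  for (t in seq_along(ds$slides)) {
    sl <- ds$slides[[t]]
    emb <- sl$embeddings
    colnames(emb) <- paste0("pc", seq_len(ncol(emb)))
    df <- cbind(sl$spots, as.data.frame(emb))
    utils::write.csv(df, file.path(outdir, paste0(sl$slide_id, ".csv")),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(sl$counts))
      write_counts_dir(sl, file.path(outdir, sl$slide_id))
  }
  tl <- do.call(rbind, lapply(seq_along(ds$slides), function(t)
    data.frame(slide_id = ds$slides[[t]]$slide_id,
               spot_id = ds$slides[[t]]$spots$spot_id,
               label = sim$truth$labels[[t]], stringsAsFactors = FALSE)))
  utils::write.csv(tl, file.path(outdir, "truth_labels.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- sim$config
  cfg$lattice <- as.data.frame(cfg$lattice)
  jsonlite::write_json(unclass(cfg), file.path(outdir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor")
  invisible(outdir)
}
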