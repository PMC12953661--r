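# File formats: tab-separated tables and matrices, a minimal single-file
# uncompressed NIfTI-1 (.nii) reader/writer, MRtrix TCK (Float32LE)
# streamlines, and a JSON-lines polyline dialect for text fixtures.
# No R NIfTI/streamline package is available offline, so the two binary
# formats are implemented here against their published fixed layouts.

#' Write / read a square matrix as a tab-separated table
#'
#' Values are serialized at 9 significant digits with a node-id header row;
#' the round trip is lossless within that precision.
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @return `read_matrix_tsv` returns the matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(signif(m, 9))
  colnames(df) <- colnames(m) %||% seq_len(ncol(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- tryCatch(read.delim(path, check.names = FALSE),
                 error = function(e) stop_data("cannot parse matrix file ",
                                               path, ": ", conditionMessage(e)))
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop_data("matrix file ", path, " is not square (", nrow(m), " x ",
              ncol(m), ")")
  if (any(!is.finite(m)))
    stop_data("matrix file ", path, " contains non-numeric entries")
  rownames(m) <- colnames(m)
  m
}

#' Write / read cohort-style tables
#'
#' Tab-separated with a header row.
#'
#' @param df data.frame.
#' @param path file path.
#' @export
write_table_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

nifti_datatypes <- c(`2` = "uint8", `4` = "int16", `8` = "int32",
                     `16` = "float32", `64` = "float64")

#' Write a 3-D array as an uncompressed NIfTI-1 file
#'
#' Single-file .nii, little-endian, identity orientation with isotropic
#' voxel size recorded in pixdim and the sform rows.
#'
#' @param arr 3-D numeric/integer/logical array.
#' @param path output path (.nii).
#' @param voxel_size voxel edge length in mm.
#' @param datatype `"int32"` or `"float32"`.
#' @export
write_nifti <- function(arr, path, voxel_size = 1,
                        datatype = c("int32", "float32")) {
  datatype <- match.arg(datatype)
  dims <- dim(arr)
  stopifnot(length(dims) == 3)
  code <- if (datatype == "int32") 8L else 16L
  bitpix <- 32L
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(n) writeBin(raw(n), con)
  wi(348, 4)                       # sizeof_hdr
  wc(35); writeBin(as.raw(0), con) # data_type, db_name, extents, ... filler
  wi(c(3, dims, 1, 1, 1, 1), 2)    # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)         # intent_p1..3, intent_code
  wi(code, 2); wi(bitpix, 2); wi(0, 2)   # datatype, bitpix, slice_start
  wf(c(1, rep(voxel_size, 3), 0, 0, 0, 0))  # pixdim[8]
  wf(352); wf(1); wf(0)            # vox_offset, scl_slope, scl_inter
  wi(0, 2); writeBin(as.raw(c(0, 2)), con)  # slice_end, slice_code, xyzt_units = mm
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(c(0, 0), 4)                   # glmax, glmin
  wc(80 + 24)                      # descrip, aux_file
  wi(0, 2); wi(1, 2)               # qform_code = 0, sform_code = 1
  wf(rep(0, 6))                    # quatern b,c,d + qoffset x,y,z
  wf(c(voxel_size, 0, 0, 0))       # srow_x
  wf(c(0, voxel_size, 0, 0))       # srow_y
  wf(c(0, 0, voxel_size, 0))       # srow_z
  wc(16)                           # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  wc(4)                            # extension flag
  if (datatype == "int32") wi(as.vector(arr), 4) else wf(as.vector(arr))
  invisible(path)
}

#' Read an uncompressed NIfTI-1 file
#'
#' @param path .nii path.
#' @return list with `data` (array), `voxel_size` (pixdim 1..3), `datatype`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n, size = size,
                                  endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L))
    stop_data(path, " is not a little-endian NIfTI-1 file (sizeof_hdr = ",
              hdr_size, ")")
  invisible(readBin(con, "raw", 36))
  dim8 <- ri(8, 2)
  invisible(rf(3)); invisible(ri(1, 2))
  dtype <- ri(1, 2); bitpix <- ri(1, 2); invisible(ri(1, 2))
  pixdim <- rf(8)
  vox_offset <- rf(1)
  dname <- nifti_datatypes[as.character(dtype)]
  if (is.na(dname)) stop_data("unsupported NIfTI datatype code ", dtype)
  ndim <- dim8[1]
  dims <- dim8[2:(1 + max(ndim, 3))]
  dims <- dims[dims > 0]
  if (length(dims) != 3) stop_data("only 3-D NIfTI volumes are supported")
  seek(con, vox_offset)
  n <- prod(dims)
  data <- switch(dname,
    uint8 = readBin(con, "integer", n, size = 1, signed = FALSE),
    int16 = readBin(con, "integer", n, size = 2, endian = "little"),
    int32 = readBin(con, "integer", n, size = 4, endian = "little"),
    float32 = readBin(con, "numeric", n, size = 4, endian = "little"),
    float64 = readBin(con, "numeric", n, size = 8, endian = "little"))
  list(data = array(data, dim = dims), voxel_size = pixdim[2:4],
       datatype = dname)
}

#' Write / read MRtrix TCK streamline files
#'
#' Float32 little-endian triplets, streamlines separated by NaN triplets and
#' terminated by an Inf triplet, per the published format.
#'
#' @param tractogram a `tractogram` (FA is not stored by TCK; it round-trips
#'   through the JSON-lines dialect instead).
#' @param path output path (.tck).
#' @export
write_tck <- function(tractogram, path) {
  n <- length(tractogram$streamlines)
  hdr_base <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ", n,
                     "\nfile: . ")
  # the offset field includes its own digits; fixed-width keeps it simple
  offset <- nchar(hdr_base) + 10 + nchar("\nEND\n")
  hdr <- paste0(hdr_base, formatC(offset, width = 10), "\nEND\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (pts in tractogram$streamlines) {
    writeBin(as.numeric(t(pts)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_tck
#' @export
read_tck <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (!identical(rawToChar(raw[1:13]), "mrtrix tracks"))
    stop_data(path, " is not a TCK file")
  # header is newline-delimited text up to the "\nEND\n" marker; the payload
  # is binary, so locate the marker at byte level before text conversion
  pat <- charToRaw("\nEND\n")
  hits <- which(raw == pat[1])
  pos <- NA_integer_
  for (i in hits) {
    if (i + 4 <= length(raw) && identical(raw[i:(i + 4)], pat)) { pos <- i; break }
  }
  if (is.na(pos)) stop_data("TCK header END marker not found in ", path)
  lines <- strsplit(rawToChar(raw[1:(pos - 1)]), "\n", fixed = TRUE)[[1]]
  kv <- lines[-1]
  get <- function(key) {
    hit <- grep(paste0("^", key, ":"), kv, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(paste0("^", key, ":"), "", hit[1]))
  }
  if (!identical(get("datatype"), "Float32LE"))
    stop_data("unsupported TCK datatype: ", get("datatype"))
  off <- as.numeric(strsplit(get("file"), "\\s+")[[1]][2])
  vals <- readBin(raw[(off + 1):length(raw)], "numeric",
                  (length(raw) - off) / 4, size = 4, endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  sl <- list()
  cur <- NULL
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (all(is.infinite(p))) break
    if (all(is.nan(p))) {
      if (!is.null(cur)) sl[[length(sl) + 1]] <- cur
      cur <- NULL
    } else cur <- rbind(cur, p)
  }
  structure(list(streamlines = lapply(sl, function(m) {
    dimnames(m) <- NULL; m
  }), fa = rep(NA_real_, length(sl))), class = "tractogram")
}

#' Write / read the JSON-lines streamline fixture dialect
#'
#' One JSON object per line: `{"points": [[x,y,z], ...], "fa": value}`.
#' Text-only, so usable as an in-repo fixture format.
#'
#' @param tractogram a `tractogram`.
#' @param path output path (.jsonl).
#' @export
write_streamlines_jsonl <- function(tractogram, path) {
  lines <- vapply(seq_along(tractogram$streamlines), function(i) {
    jsonlite::toJSON(list(points = unname(tractogram$streamlines[[i]]),
                          fa = tractogram$fa[i]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_streamlines_jsonl
#' @export
read_streamlines_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sl <- vector("list", length(lines))
  fa <- numeric(length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop_data("malformed JSON at line ", i,
                                                  " of ", path))
    sl[[i]] <- matrix(as.numeric(obj$points), ncol = 3)
    fa[i] <- obj$fa %||% NA_real_
  }
  structure(list(streamlines = sl, fa = fa), class = "tractogram")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a `sim_config` (or plain list of overrides).
#' @param path .json path.
#' @export
write_config_json <- function(config, path) {
  prep <- unclass(config)
  # open-ended named vectors serialize as JSON objects so names survive
  prep$metric_effect_profile <- lapply(prep$metric_effect_profile, as.list)
  if (length(prep$impairment_model$coef))
    prep$impairment_model$coef <- as.list(prep$impairment_model$coef)
  jsonlite::write_json(prep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  raw <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop_config("cannot parse config ",
                                                  path, ": ",
                                                  conditionMessage(e)))
  defaults <- sim_config()
  known <- intersect(names(raw), names(unclass(defaults)))
  cfg <- modifyList(unclass(defaults), raw[known])
  # JSON drops names of atomic vectors and matrix dimnames; restore them
  # positionally against the documented layouts
  renm <- function(x, nm) setNames(as.numeric(x), nm)
  if ("sex_ratio" %in% known) cfg$sex_ratio <- renm(cfg$sex_ratio, c("hc", "aoms", "loms"))
  if ("education_p" %in% known) cfg$education_p <- renm(cfg$education_p, c("hc", "aoms", "loms"))
  if ("pms_p" %in% known) cfg$pms_p <- renm(cfg$pms_p, c("aoms", "loms"))
  if ("lv_meanlog" %in% known) cfg$lv_meanlog <- renm(cfg$lv_meanlog, c("aoms", "loms"))
  if ("disc_means" %in% known)
    cfg$disc_means <- matrix(as.numeric(cfg$disc_means), nrow = 2,
                             dimnames = list(c("inter", "intra"),
                                             c("hc", "aoms", "loms")))
  if ("metric_effect_profile" %in% known)
    cfg$metric_effect_profile <- lapply(cfg$metric_effect_profile, unlist)
  if ("impairment_model" %in% known && length(cfg$impairment_model$coef))
    cfg$impairment_model$coef <- unlist(cfg$impairment_model$coef)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}
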