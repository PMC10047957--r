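#' Read a C3D motion-capture file
#'
#' Reads the de-facto standard binary capture format written by optical
#' motion-capture systems: 512-byte header, parameter section
#' (POINT/ANALOG groups) and interleaved 3D point + analog data.  Supports
#' Intel-processor files with either floating-point or scaled-integer data,
#' which covers modern exports.  Point units are converted to mm
#' (`POINT:UNITS` of `"m"` is scaled by 1000), marker labels are normalized
#' to the canonical vocabulary through an alias map, and samples with a
#' negative residual (invalid/occluded points) are flagged missing, never
#' zero-filled.
#'
#' @param path path to a `.c3d` file.
#' @param condition,side,subject_id trial metadata not carried by the C3D
#'   point section; defaults `"BF"`, `"right"`, `"S01"`.
#' @param alias_map named character vector `c(alias = canonical)`; defaults
#'   to the packaged map from [read_alias_map()].  Pass `character(0)` to
#'   keep raw labels.
#' @return a [trial_recording()].
#' @export
read_c3d <- function(path, condition = "BF", side = "right",
                     subject_id = "S01", alias_map = read_alias_map()) {
  if (!file.exists(path)) stop("C3D file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 512)
  if (length(hdr) < 512 || as.integer(hdr[2]) != 0x50)
    stop("not a C3D file (bad magic byte): ", path, call. = FALSE)
  u16 <- function(raw, i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  param_block <- as.integer(hdr[1])
  npoints <- u16(hdr, 3)
  analog_per_frame <- u16(hdr, 5)     # total analog values per 3D frame
  first_frame <- u16(hdr, 7)
  last_frame <- u16(hdr, 9)
  point_scale <- readBin(hdr[13:16], "double", size = 4, endian = "little")
  data_block <- u16(hdr, 17)
  analog_sub <- u16(hdr, 19)          # analog samples per frame per channel
  point_rate <- readBin(hdr[21:24], "double", size = 4, endian = "little")
  if (npoints == 0L) stop("C3D contains zero markers: ", path, call. = FALSE)

  params <- c3d_read_params(con, param_block)
  gp <- function(group, name, default = NULL) {
    v <- params[[group]][[name]]
    if (is.null(v)) default else v
  }
  # parameter section overrides header where present
  npoints <- as.integer(gp("POINT", "USED", npoints))
  point_rate <- as.numeric(gp("POINT", "RATE", point_rate))
  point_scale <- as.numeric(gp("POINT", "SCALE", point_scale))
  data_block <- as.integer(gp("POINT", "DATA_START", data_block))
  nframes <- as.integer(gp("POINT", "FRAMES", last_frame - first_frame + 1L))
  units <- trimws(gp("POINT", "UNITS", "mm")[1])
  labels <- trimws(gp("POINT", "LABELS", sprintf("M%03d", seq_len(npoints))))
  labels <- labels[seq_len(npoints)]
  nchan <- if (analog_sub > 0) analog_per_frame %/% analog_sub else 0L
  nchan <- as.integer(gp("ANALOG", "USED", nchan))
  alabels <- trimws(gp("ANALOG", "LABELS", sprintf("A%02d", seq_len(max(nchan, 0)))))
  a_gen <- as.numeric(gp("ANALOG", "GEN_SCALE", 1))
  a_scale <- as.numeric(gp("ANALOG", "SCALE", rep(1, max(nchan, 0))))
  a_off <- as.numeric(gp("ANALOG", "OFFSET", rep(0, max(nchan, 0))))

  is_float <- point_scale < 0
  seek(con, (data_block - 1L) * 512L)
  per_frame <- npoints * 4L + nchan * analog_sub
  if (is_float) {
    raw <- readBin(con, "double", n = per_frame * nframes, size = 4,
                   endian = "little")
  } else {
    raw <- readBin(con, "integer", n = per_frame * nframes, size = 2,
                   signed = TRUE, endian = "little")
  }
  if (length(raw) < per_frame * nframes)
    stop("truncated C3D data section: ", path, call. = FALSE)
  dat <- matrix(raw, nrow = per_frame, ncol = nframes)

  scale_abs <- if (is_float) 1 else abs(point_scale)
  unit_mult <- if (tolower(units) %in% c("m", "meter", "metre")) 1000 else 1
  markers <- vector("list", npoints)
  names(markers) <- labels
  for (j in seq_len(npoints)) {
    rows <- (j - 1L) * 4L + 1:4
    xyz <- t(dat[rows[1:3], , drop = FALSE]) * scale_abs * unit_mult
    resid <- dat[rows[4], ]
    if (!is_float) resid <- resid # int residual: negative word = invalid
    xyz[resid < 0, ] <- NA_real_
    colnames(xyz) <- c("x", "y", "z")
    markers[[j]] <- xyz
  }
  analog <- list()
  if (nchan > 0L) {
    a <- dat[npoints * 4L + seq_len(nchan * analog_sub), , drop = FALSE]
    # per frame layout: one subsample of every channel, repeated
    for (k in seq_len(nchan)) {
      idx <- seq(k, nchan * analog_sub, by = nchan)
      analog[[alabels[k]]] <- (as.numeric(a[idx, ]) - a_off[k]) *
        a_scale[k] * a_gen
    }
  }
  trial_recording(
    trial_id = sub("\\.c3d$", "", basename(path), ignore.case = TRUE),
    condition = condition, side = side, markers = markers,
    marker_rate = point_rate, analog = analog,
    analog_rate = if (nchan > 0L) point_rate * analog_sub else NA_real_,
    subject_id = subject_id) |>
    apply_alias_map(alias_map)
}

# Parse the parameter section into list(GROUP = list(PARAM = value, ...))
c3d_read_params <- function(con, param_block) {
  seek(con, (param_block - 1L) * 512L)
  head4 <- readBin(con, "raw", 4)
  nblocks <- as.integer(head4[3])
  proc <- as.integer(head4[4])
  if (proc != 84L)
    stop("unsupported C3D processor type ", proc, " (only Intel/84)", call. = FALSE)
  buf <- readBin(con, "raw", nblocks * 512L - 4L)
  pos <- 1L
  rd_i8 <- function(p) { v <- as.integer(buf[p]); if (v > 127L) v - 256L else v }
  rd_i16 <- function(p) {
    v <- as.integer(buf[p]) + 256L * as.integer(buf[p + 1L])
    if (v > 32767L) v - 65536L else v
  }
  groups <- list(); gnames <- list()
  repeat {
    if (pos + 1L > length(buf)) break
    nname <- rd_i8(pos)
    gid <- rd_i8(pos + 1L)
    if (nname == 0L || gid == 0L) break
    nname <- abs(nname)
    name <- rawToChar(buf[pos + 1L + seq_len(nname)])
    p <- pos + 2L + nname
    offset <- rd_i16(p)
    nxt <- p + 2L + offset - 2L  # offset counted from the end of its own field
    if (gid < 0L) {                       # group definition
      gnames[[as.character(-gid)]] <- name
      if (is.null(groups[[name]])) groups[[name]] <- list()
    } else {                              # parameter
      p <- p + 2L
      dtype <- rd_i8(p); ndim <- rd_i8(p + 1L)
      dims <- if (ndim > 0) vapply(seq_len(ndim), function(k) as.integer(buf[p + 1L + k]),
                                   integer(1)) else integer(0)
      p <- p + 2L + ndim
      nelem <- if (length(dims)) prod(dims) else 1L
      esize <- c(`-1` = 1L, `1` = 1L, `2` = 2L, `4` = 4L)[[as.character(dtype)]]
      nbytes <- nelem * esize
      bytes <- buf[p - 1L + seq_len(nbytes)]
      value <- switch(as.character(dtype),
        `-1` = {
          if (length(dims) >= 2L) {
            w <- dims[1]; n <- prod(dims[-1])
            vapply(seq_len(n), function(k)
              rawToChar(bytes[(k - 1L) * w + seq_len(w)]), character(1))
          } else rawToChar(bytes)
        },
        `1` = as.integer(bytes),
        `2` = readBin(bytes, "integer", n = nelem, size = 2, signed = TRUE,
                      endian = "little"),
        `4` = readBin(bytes, "double", n = nelem, size = 4, endian = "little"))
      gname <- gnames[[as.character(gid)]] %||% as.character(gid)
      groups[[gname]][[name]] <- value
    }
    if (offset == 0L) break
    pos <- nxt
  }
  groups
}

#' @rdname read_c3d
#' @param trial a [trial_recording()] to serialize; positions are written as
#'   floating-point values, missing samples as invalid points (negative
#'   residual).
#' @param units unit string recorded in `POINT:UNITS` (default `"mm"`); the
#'   stored coordinates are the trial's values interpreted in these units.
#' @return [write_c3d()] returns `path` invisibly.
#' @export
write_c3d <- function(trial, path, units = "mm") {
  stopifnot(inherits(trial, "TrialRecording"))
  npoints <- length(trial$markers)
  nframes <- n_frames(trial)
  nchan <- length(trial$analog)
  analog_sub <- if (nchan > 0L)
    as.integer(round(trial$analog_rate / trial$marker_rate)) else 0L

  labels <- names(trial$markers)
  alabels <- if (nchan) names(trial$analog) else character(0)
  pad_labels <- function(v, w) vapply(v, function(s)
    formatC(substr(s, 1, w), width = w, flag = "-"), character(1))
  lab_w <- max(4L, min(30L, max(nchar(labels))))
  alab_w <- if (nchan) max(4L, min(30L, max(nchar(alabels)))) else 4L

  par_rec <- function(name, gid, payload) {
    c(as.raw(nchar(name)), as.raw(bitwAnd(gid + 256L, 255L)),
      charToRaw(name), payload)
  }
  i16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  f32 <- function(x) writeBin(as.numeric(x), raw(), size = 4, endian = "little")
  u8 <- function(x) as.raw(bitwAnd(as.integer(x) + 256L, 255L))
  param_bytes <- function(dtype, dims, data_raw, last = FALSE) {
    body <- c(u8(dtype), u8(length(dims)), as.raw(as.integer(dims)), data_raw,
              as.raw(0L))  # zero-length description
    off <- if (last) 0L else length(body) + 2L
    c(i16(off), body)
  }
  group_bytes <- function(last = FALSE) {
    body <- as.raw(0L)   # zero-length description
    off <- if (last) 0L else length(body) + 2L
    c(i16(off), body)
  }

  recs <- list(
    par_rec("POINT", -1L, group_bytes()),
    par_rec("USED", 1L, param_bytes(2, integer(0), i16(npoints))),
    par_rec("FRAMES", 1L, param_bytes(2, integer(0), i16(nframes))),
    par_rec("SCALE", 1L, param_bytes(4, integer(0), f32(-1))),
    par_rec("RATE", 1L, param_bytes(4, integer(0), f32(trial$marker_rate))),
    par_rec("UNITS", 1L, param_bytes(-1, nchar(units), charToRaw(units))),
    par_rec("LABELS", 1L, param_bytes(-1, c(lab_w, npoints),
      charToRaw(paste(pad_labels(labels, lab_w), collapse = "")))))
  ds_idx <- length(recs) + 1L
  recs[[ds_idx]] <- par_rec("DATA_START", 1L,
    param_bytes(2, integer(0), i16(0)))   # patched below
  if (nchan > 0L) {
    recs <- c(recs, list(
      par_rec("ANALOG", -2L, group_bytes()),
      par_rec("USED", 2L, param_bytes(2, integer(0), i16(nchan))),
      par_rec("RATE", 2L, param_bytes(4, integer(0), f32(trial$analog_rate))),
      par_rec("GEN_SCALE", 2L, param_bytes(4, integer(0), f32(1))),
      par_rec("SCALE", 2L, param_bytes(4, nchan, f32(rep(1, nchan)))),
      par_rec("OFFSET", 2L, param_bytes(2, nchan, i16(rep(0, nchan)))),
      par_rec("LABELS", 2L, param_bytes(-1, c(alab_w, nchan),
        charToRaw(paste(pad_labels(alabels, alab_w), collapse = ""))))))
  }
  finish <- function(recs) {
    body <- do.call(c, recs)
    nblocks <- ceiling((length(body) + 4L) / 512L)
    sec <- c(as.raw(c(0x01, 0x50)), u8(nblocks), u8(84L), body)
    c(sec, raw(nblocks * 512L - length(sec)))
  }
  # two passes: parameter section length fixes DATA_START
  psec <- finish(recs)
  data_block <- 2L + length(psec) %/% 512L
  recs[[ds_idx]] <- par_rec("DATA_START", 1L,
    param_bytes(2, integer(0), i16(data_block)))
  psec <- finish(recs)

  # header block
  hdr <- raw(512)
  hdr[1] <- as.raw(2L); hdr[2] <- as.raw(0x50)
  hdr[3:4] <- i16(npoints)
  hdr[5:6] <- i16(nchan * analog_sub)
  hdr[7:8] <- i16(1L); hdr[9:10] <- i16(nframes)
  hdr[13:16] <- f32(-1)
  hdr[17:18] <- i16(data_block)
  hdr[19:20] <- i16(analog_sub)
  hdr[21:24] <- f32(trial$marker_rate)

  per_frame <- npoints * 4L + nchan * analog_sub
  dat <- matrix(0, nrow = per_frame, ncol = nframes)
  for (j in seq_len(npoints)) {
    m <- trial$markers[[j]]
    bad <- !stats::complete.cases(m)
    m[bad, ] <- 0
    rows <- (j - 1L) * 4L + 1:4
    dat[rows[1:3], ] <- t(m)
    dat[rows[4], ] <- ifelse(bad, -1, 0)
  }
  if (nchan > 0L) {
    a <- matrix(0, nchan * analog_sub, nframes)
    for (k in seq_len(nchan)) {
      ch <- trial$analog[[k]]
      length(ch) <- analog_sub * nframes  # pad with NA then zero-fill
      ch[is.na(ch)] <- 0
      a[seq(k, nchan * analog_sub, by = nchan), ] <-
        matrix(ch, analog_sub, nframes)
    }
    dat[npoints * 4L + seq_len(nchan * analog_sub), ] <- a
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(psec, con)
  writeBin(as.numeric(dat), con, size = 4, endian = "little")
  invisible(path)
}
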