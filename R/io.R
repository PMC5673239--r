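#' Read a PDB structure into a snapshot
#'
#' Parses ATOM/HETATM records through `bio3d::read.pdb`. Multi-model
#' files contribute model 1 only; where alternate locations exist, only
#' altloc A is kept. Elements come from the element column when present,
#' otherwise from the leading letter of the atom name.
#'
#' @param path path to a PDB file.
#' @return a [snapshot()] (with an extra `type` column flagging HETATM).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file ", path,
                                           ": ", conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no ATOM records in ", path)
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, ]
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- toupper(substr(gsub("[^A-Za-z].*", "", at$elety[bad]), 1, 1))
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = at$elety, elem = elem, type = at$type,
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop("duplicate atom record in ", path, ": chain ", atoms$chain[dup],
         " residue ", atoms$resno[dup], " atom ", atoms$elety[dup])
  }
  snapshot(atoms, cbind(at$x, at$y, at$z))
}

#' Fetch a PDB entry from the RCSB (cached)
#'
#' Downloads `<id>.pdb` into `dir` unless it is already there, and
#' returns the file path. Requires network access for the first call.
#'
#' @param id 4-character PDB id, e.g. `"3RIF"`.
#' @param dir cache directory.
#' @export
fetch_pdb <- function(id, dir = file.path(tempdir(), "pdb_cache")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(dir, paste0(toupper(id), ".pdb"))
  if (file.exists(dest)) return(dest)
  url <- paste0("https://files.rcsb.org/download/", toupper(id), ".pdb")
  ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE) == 0,
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    stop("could not download PDB entry ", id,
         " (no network access?); place ", id, ".pdb in ", dir, " manually")
  }
  dest
}

#' Read a DCD trajectory
#'
#' Reads a CHARMM/NAMD DCD file through `bio3d::read.dcd` and attaches
#' the atom roster of a matching topology snapshot.
#'
#' @param path path to the DCD file.
#' @param top a [snapshot()] providing the atom roster (its atom count
#'   must match the file).
#' @param frame_interval frame spacing in ps (DCD headers do not carry
#'   reliable time units).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, top, frame_interval = 10) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  nat <- ncol(xyz) / 3
  if (nat != nrow(top$atoms)) {
    stop("atom-count mismatch: trajectory has ", nat, " atoms, topology has ",
         nrow(top$atoms))
  }
  nf <- nrow(xyz)
  arr <- array(NA_real_, c(nat, 3, nf))
  for (f in seq_len(nf)) {
    arr[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  trajectory(top$atoms, arr, box = top$box, frame_interval = frame_interval)
}

#' Write a trajectory as a DCD file
#'
#' Minimal single-precision CHARMM-format writer (little-endian, no unit
#' cell records), sufficient for interchange with standard MD analysis
#' tools.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  nf <- n_frames(traj)
  nat <- nrow(traj$atoms)
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran unformatted record: length, payload, length
    raw_con <- rawConnection(raw(0), "wb")
    writer(raw_con)
    payload <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(length(payload), con, size = 4, endian = "little")
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4, endian = "little")
  }
  dt <- if (nf > 1) diff(traj$times[1:2]) else 1
  rec(function(c2) {
    writeChar("CORD", c2, nchars = 4, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
    icntrl[20] <- 24L
    writeBin(as.integer(icntrl[1:9]), c2, size = 4, endian = "little")
    writeBin(as.numeric(dt), c2, size = 4, endian = "little")  # delta slot
    writeBin(as.integer(icntrl[11:20]), c2, size = 4, endian = "little")
  })
  rec(function(c2) {
    writeBin(1L, c2, size = 4, endian = "little")
    writeChar(formatC("generated by gatemetrics", width = -80), c2,
              nchars = 80, eos = NULL)
  })
  rec(function(c2) writeBin(as.integer(nat), c2, size = 4, endian = "little"))
  for (f in seq_len(nf)) {
    for (d in 1:3) {
      rec(function(c2) writeBin(as.numeric(traj$xyz[, d, f]), c2, size = 4,
                                endian = "little"))
    }
  }
  invisible(path)
}

#' Write an observable series as TSV
#'
#' One header comment line with the label and units, a column header
#' (`time_ps` plus the value columns), then one row per frame. Decimal
#' points are locale-independent.
#'
#' @param series an [obs_series()].
#' @param path output path.
#' @param digits significant digits (default 8).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, digits = 8) {
  if (!inherits(series, "obs_series")) stop("series must be an obs_series")
  if (length(series$times) == 0) stop("refusing to write an empty series")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", series$label, " [", series$units, "]"), con)
  writeLines(paste(c("time_ps", colnames(series$values)), collapse = "\t"), con)
  body <- cbind(series$times, series$values)
  lines <- apply(body, 1, function(row)
    paste(formatC(row, digits = digits, format = "g"), collapse = "\t"))
  writeLines(lines, con)
  invisible(path)
}

#' Read an observable series written by [write_series()]
#' @param path TSV path.
#' @return an [obs_series()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("series file not found: ", path)
  header <- readLines(path, n = 2)
  meta <- regmatches(header[1], regexec("^# (.*) \\[(.*)\\]$", header[1]))[[1]]
  d <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                         check.names = FALSE)
  obs_series(d[[1]], as.matrix(d[, -1, drop = FALSE]),
             label = if (length(meta) == 3) meta[2] else "",
             units = if (length(meta) == 3) meta[3] else "")
}
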