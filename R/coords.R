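#' Atomic snapshot container
#'
#' A `snapshot` couples an atom table with one set of Cartesian coordinates.
#' It is the unit every observable in the package operates on. Coordinates
#' are stored in Angstrom, time in picoseconds.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`
#'   (3-letter residue name), `elety` (atom name, e.g. `"CA"`), and `elem`
#'   (element symbol). A `type` column (`"ATOM"`/`"HETATM"`) is optional.
#' @param xyz numeric matrix with one row per atom and columns x, y, z (A).
#' @param box optional numeric length-3 orthorhombic box lengths (A).
#' @param time frame time in ps.
#' @return an object of class `snapshot`.
#' @export
snapshot <- function(atoms, xyz, box = NULL, time = 0) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("chain", "resno", "resid", "elety", "elem")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table is missing column(s): ",
                         paste(miss, collapse = ", "))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 || nrow(xyz) != nrow(atoms)) {
    stop("xyz must be an n x 3 matrix matching the atom table (",
         nrow(atoms), " atoms)")
  }
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, resno, elety) atom key: ",
         key[which(duplicated(key))[1]])
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
      stop("box must be three positive lengths (A)")
    }
  }
  structure(list(atoms = atoms, xyz = unname(xyz), box = box,
                 time = as.numeric(time)),
            class = "snapshot")
}

#' @export
print.snapshot <- function(x, ...) {
  cat("snapshot:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chains, t =", x$time, "ps\n")
  invisible(x)
}

#' Select atom indices in a snapshot
#'
#' Filters by any combination of chain, residue number, residue name, atom
#' name and element. `NULL` means no constraint.
#'
#' @param snap a [snapshot()] (or a bare atom table).
#' @param chain,resno,resid,elety,elem optional filters (vectors allowed).
#' @return integer vector of atom indices.
#' @export
atom_select <- function(snap, chain = NULL, resno = NULL, resid = NULL,
                        elety = NULL, elem = NULL) {
  at <- if (inherits(snap, "snapshot")) snap$atoms else snap
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(resid)) keep <- keep & at$resid %in% resid
  if (!is.null(elety)) keep <- keep & at$elety %in% elety
  if (!is.null(elem))  keep <- keep & at$elem %in% elem
  which(keep)
}

# C-alpha indices of a chain restricted to a residue-number interval.
ca_indices <- function(snap, chain, range) {
  at <- snap$atoms
  which(at$chain == chain & at$elety == "CA" &
          at$resno >= range[1] & at$resno <= range[2])
}

#' Trajectory container
#'
#' An ordered set of snapshots sharing one atom roster, stored as a
#' 3-dimensional coordinate array for speed.
#'
#' @param atoms atom table as in [snapshot()].
#' @param xyz numeric array of dim `c(n_atoms, 3, n_frames)`.
#' @param times frame times in ps (strictly increasing). Defaults to
#'   `frame_interval * (0:(n_frames-1))`.
#' @param box optional box lengths (A), shared by all frames.
#' @param frame_interval nominal spacing in ps used when `times` is absent.
#' @return an object of class `gm_trajectory`.
#' @export
trajectory <- function(atoms, xyz, times = NULL, box = NULL,
                       frame_interval = 10) {
  if (length(dim(xyz)) != 3 || dim(xyz)[2] != 3) {
    stop("xyz must be an n_atoms x 3 x n_frames array")
  }
  nf <- dim(xyz)[3]
  if (is.null(times)) times <- frame_interval * (seq_len(nf) - 1)
  if (length(times) != nf) stop("times length must equal the frame count")
  if (nf > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  # validate the roster once through the snapshot constructor
  s1 <- snapshot(atoms, matrix(xyz[, , 1], ncol = 3), box = box,
                 time = times[1])
  structure(list(atoms = s1$atoms, xyz = xyz, times = as.numeric(times),
                 box = s1$box),
            class = "gm_trajectory")
}

#' @export
print.gm_trajectory <- function(x, ...) {
  cat("trajectory:", n_frames(x), "frames,", nrow(x$atoms), "atoms, dt =",
      if (n_frames(x) > 1) signif(diff(x$times[1:2]), 4) else NA, "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Extract one frame of a trajectory as a snapshot
#' @param traj a [trajectory()].
#' @param i frame index (1-based).
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range")
  snapshot(traj$atoms, matrix(traj$xyz[, , i], ncol = 3), box = traj$box,
           time = traj$times[i])
}

#' Build a trajectory from a list of snapshots
#' @param snaps list of [snapshot()] objects with identical atom rosters.
#' @export
trajectory_from_snapshots <- function(snaps) {
  stopifnot(length(snaps) >= 1)
  a0 <- snaps[[1]]$atoms
  key0 <- paste(a0$chain, a0$resno, a0$elety)
  xyz <- array(NA_real_, c(nrow(a0), 3, length(snaps)))
  for (i in seq_along(snaps)) {
    ai <- snaps[[i]]$atoms
    if (!identical(paste(ai$chain, ai$resno, ai$elety), key0)) {
      stop("snapshot ", i, " has a different atom roster")
    }
    xyz[, , i] <- snaps[[i]]$xyz
  }
  trajectory(a0, xyz, times = vapply(snaps, `[[`, numeric(1), "time"),
             box = snaps[[1]]$box)
}
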