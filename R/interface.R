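# Atomic masses for heavy-atom center-of-mass calculations.
.atomic_mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
                  H = 1.008)

# Heavy-atom center of mass of one residue.
.residue_com <- function(snap, chain, resno) {
  idx <- atom_select(snap, chain = chain, resno = resno)
  idx <- idx[snap$atoms$elem[idx] != "H"]
  if (!length(idx)) stop("residue ", chain, ":", resno, " has no heavy atoms")
  m <- .atomic_mass[snap$atoms$elem[idx]]
  m[is.na(m)] <- 12  # unknown elements weighted like carbon
  colSums(snap$xyz[idx, , drop = FALSE] * m) / sum(m)
}

# Single-atom coordinate lookup with a clear error.
.atom_xyz <- function(snap, chain, resno, elety) {
  idx <- atom_select(snap, chain = chain, resno = resno, elety = elety)
  if (length(idx) != 1) {
    stop("atom ", elety, " of residue ", resno, " (chain ", chain, ") ",
         if (length(idx)) "is ambiguous" else "is missing")
  }
  snap$xyz[idx, ]
}

#' Membrane-plane projection of the M2-M3 loop proline
#'
#' After least-squares superposition of the snapshot's TM C-alpha atoms
#' onto a reference structure, the heavy-atom center of mass of the
#' conserved M2-M3 loop proline (P268 in GluCl) of each subunit is
#' projected onto the plane perpendicular to the receptor axis. The
#' in-plane (x, y) coordinates and the radial distance to the pore center
#' track the out -> in translocation of the loop during pore closing.
#'
#' @param snap a [snapshot()] to analyze.
#' @param ref reference [snapshot()] (e.g. the active-state structure)
#'   defining the frame; the TM superposition removes global drift.
#' @param topo a [receptor_topology()] with key residue `M2M3_proline`.
#' @param af axis frame of the *reference* (computed when omitted).
#' @return data.frame with one row per subunit: `chain`, `x`, `y` (A, in
#'   the membrane plane), `radial` (A, distance to the pore axis).
#' @export
project_interface_proline <- function(snap, ref, topo,
                                      af = pore_axis(ref, topo)) {
  pro <- key_residue(topo, "M2M3_proline")
  fit <- superpose(snap, ref, selection_spec(topo, domain = "tm"))
  if (fit$rmsd > 10) {
    warning("TM superposition RMSD is ", round(fit$rmsd, 1),
            " A - is the reference the right structure?")
  }
  moved <- apply_transform(snap, fit)
  out <- lapply(topo$chains, function(ch) {
    com <- .residue_com(moved, ch, pro)
    p <- axis_coords(matrix(com, 1, 3), af)
    data.frame(chain = ch, x = p[1, 1], y = p[1, 2],
               radial = sqrt(p[1, 1]^2 + p[1, 2]^2))
  })
  do.call(rbind, out)
}

#' Vertical beta1-beta2 / M2-M3 loop separation (Delta Z)
#'
#' Distance, projected on the receptor axis, between the C-alpha of the
#' M2-M3 loop proline (P268) and the C-alpha at the tip of the beta1-beta2
#' loop (V45), averaged over subunits. Reported unsigned by default (the
#' quantity grows from ~5 A in the active state to ~7 A upon closing);
#' `signed = TRUE` keeps the convention z(beta1-beta2 tip) - z(proline).
#'
#' @param snap a [snapshot()].
#' @param topo a [receptor_topology()] with key residues `M2M3_proline`
#'   and `beta12_tip`.
#' @param af an `axis_frame` (computed from `snap` when omitted).
#' @param signed keep the sign of z(tip) - z(proline)?
#' @return list with `per_subunit` (named, A) and `mean`.
#' @export
delta_z <- function(snap, topo, af = pore_axis(snap, topo), signed = FALSE) {
  pro <- key_residue(topo, "M2M3_proline")
  tip <- key_residue(topo, "beta12_tip")
  vals <- vapply(topo$chains, function(ch) {
    p1 <- tryCatch(.atom_xyz(snap, ch, pro, "CA"), error = function(e) NULL)
    p2 <- tryCatch(.atom_xyz(snap, ch, tip, "CA"), error = function(e) NULL)
    if (is.null(p1) || is.null(p2)) return(NA_real_)
    sum((p2 - p1) * af$z)
  }, numeric(1))
  ok <- !is.na(vals)
  if (sum(ok) < 4) {
    stop("Delta Z requires the proline and tip C-alpha in at least 4 subunits")
  }
  v <- if (signed) vals else abs(vals)
  list(per_subunit = v, mean = mean(v[ok]))
}

#' Separation between the M2 and M3 helix centers
#'
#' Euclidean distance, per subunit, between the C-alpha centroids of the
#' M2 and M3 segments (residues 258-265 and 274-280 in GluCl). A stable
#' value across pore closing indicates the two helices move as a block.
#'
#' @param snap a [snapshot()].
#' @param topo a [receptor_topology()]; segments default to
#'   `topo$segments$m2_sep` / `topo$segments$m3_sep`.
#' @param m2_seg,m3_seg optional `c(lo, hi)` residue intervals.
#' @param chains chains to measure (default: all five).
#' @return list with `per_subunit` (named, A) and `mean`.
#' @export
m2_m3_separation <- function(snap, topo, m2_seg = NULL, m3_seg = NULL,
                             chains = topo$chains) {
  m2_seg <- m2_seg %||% topo$segments$m2_sep
  m3_seg <- m3_seg %||% topo$segments$m3_sep
  if (is.null(m2_seg) || is.null(m3_seg)) {
    stop("m2_seg/m3_seg not given and not present in topo$segments")
  }
  vals <- vapply(chains, function(ch) {
    i2 <- ca_indices(snap, ch, m2_seg)
    i3 <- ca_indices(snap, ch, m3_seg)
    if (!length(i2)) stop("chain ", ch, ": no C-alpha in M2 segment ",
                          paste(m2_seg, collapse = "-"))
    if (!length(i3)) stop("chain ", ch, ": no C-alpha in M3 segment ",
                          paste(m3_seg, collapse = "-"))
    vnorm(colMeans(snap$xyz[i2, , drop = FALSE]) -
            colMeans(snap$xyz[i3, , drop = FALSE]))
  }, numeric(1))
  list(per_subunit = vals, mean = mean(vals))
}

#' Characteristic binding-site and interface distances
#'
#' Monitors the distances the functional state of the receptor is read
#' from:
#' * `orthosteric` — C-alpha Ser150 of the principal (+) subunit to
#'   C-alpha Arg56 of the complementary (-) subunit, per interface;
#' * `allosteric` — C-alpha Gly281 (+) to C-alpha Leu218 (-), the
#'   transmembrane modulator site;
#' * `beta_expansion` — intra-subunit C-alpha Arg211 to C-alpha Val44;
#' * `lglu_restraints` — for a bound neurotransmitter (one ligand residue
#'   per interface, supplied via `ligands`): the minimum distance between
#'   the ligand side-chain carboxylate oxygens (OE1/OE2) and the basic
#'   nitrogens (NE/NH1/NH2) of Arg56 (-), and the distance between the
#'   ligand amine nitrogen (N) and the centroid of the aromatic ring
#'   atoms of Tyr151 and Tyr200 (+).
#'
#' Interfaces are paired following `topo$interface_order`.
#'
#' @param snap a [snapshot()].
#' @param topo a [receptor_topology()] declaring the key residues used by
#'   the preset (`orthosteric_plus`, `orthosteric_minus`,
#'   `allosteric_plus`, `allosteric_minus`, `beta_expansion_a/b`,
#'   `aromatic_1/2`).
#' @param preset one of `"orthosteric"`, `"allosteric"`,
#'   `"beta_expansion"`, `"lglu_restraints"`.
#' @param ligands for `lglu_restraints`: data.frame with columns `chain`
#'   and `resno` giving the ligand residue of each interface, in
#'   `interface_order` order.
#' @return data.frame of per-interface (or per-subunit) distances (A).
#' @export
site_distance <- function(snap, topo,
                          preset = c("orthosteric", "allosteric",
                                     "beta_expansion", "lglu_restraints"),
                          ligands = NULL) {
  preset <- match.arg(preset)
  pairs <- interface_pairs(topo)
  if (preset == "orthosteric" || preset == "allosteric") {
    kp <- if (preset == "orthosteric") "orthosteric_plus" else "allosteric_plus"
    km <- if (preset == "orthosteric") "orthosteric_minus" else "allosteric_minus"
    rp <- key_residue(topo, kp); rm_ <- key_residue(topo, km)
    d <- vapply(seq_len(5), function(i) {
      vnorm(.atom_xyz(snap, pairs$principal[i], rp, "CA") -
              .atom_xyz(snap, pairs$complementary[i], rm_, "CA"))
    }, numeric(1))
    return(data.frame(principal = pairs$principal,
                      complementary = pairs$complementary,
                      distance = d))
  }
  if (preset == "beta_expansion") {
    ra <- key_residue(topo, "beta_expansion_a")
    rb <- key_residue(topo, "beta_expansion_b")
    d <- vapply(topo$chains, function(ch) {
      vnorm(.atom_xyz(snap, ch, ra, "CA") - .atom_xyz(snap, ch, rb, "CA"))
    }, numeric(1))
    return(data.frame(chain = topo$chains, distance = d))
  }
  # lglu_restraints
  if (is.null(ligands) || !all(c("chain", "resno") %in% names(ligands))) {
    stop("preset 'lglu_restraints' needs ligands = data.frame(chain, resno)")
  }
  rminus <- key_residue(topo, "orthosteric_minus")  # Arg56
  y1 <- key_residue(topo, "aromatic_1")             # Tyr151
  y2 <- key_residue(topo, "aromatic_2")             # Tyr200
  ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  out <- lapply(seq_len(nrow(ligands)), function(i) {
    pl <- pairs$principal[i]; cm <- pairs$complementary[i]
    lch <- ligands$chain[i]; lrn <- ligands$resno[i]
    ox <- lapply(c("OE1", "OE2"), function(a) .atom_xyz(snap, lch, lrn, a))
    nn <- lapply(c("NE", "NH1", "NH2"), function(a)
      tryCatch(.atom_xyz(snap, cm, rminus, a), error = function(e) NULL))
    nn <- nn[!vapply(nn, is.null, logical(1))]
    if (!length(nn)) stop("no basic nitrogens found on residue ", rminus,
                          " chain ", cm)
    d_salt <- min(vapply(ox, function(o)
      min(vapply(nn, function(n) vnorm(o - n), numeric(1))), numeric(1)))
    ring_xyz <- do.call(rbind, lapply(c(y1, y2), function(rn) {
      idx <- atom_select(snap, chain = pl, resno = rn, elety = ring)
      if (!length(idx)) stop("no aromatic ring atoms for residue ", rn,
                             " chain ", pl)
      snap$xyz[idx, , drop = FALSE]
    }))
    d_cation <- vnorm(.atom_xyz(snap, lch, lrn, "N") - colMeans(ring_xyz))
    data.frame(principal = pl, complementary = cm,
               carboxylate_to_arg = d_salt, amine_to_ring = d_cation)
  })
  do.call(rbind, out)
}

#' Side-chain chi rotamer of a pore-lining residue
#'
#' Dihedral angle over the quadruple N, C-alpha, C-beta, C-gamma of the
#' given residue (default: the 9' leucine forming the constriction), with
#' the cis/trans call at |chi| < 90 degrees. `order = "literal"` uses the
#' alternative atom ordering C-alpha, C-beta, C-gamma, N.
#'
#' @param snap a [snapshot()].
#' @param topo a [receptor_topology()].
#' @param chain subunit chain id.
#' @param resno residue number; defaults to the 9' residue.
#' @param order `"standard"` (N-CA-CB-CG, the chi1 convention) or
#'   `"literal"` (CA-CB-CG-N).
#' @return a list of class `rotamer_state` with `chi` (degrees, in
#'   (-180, 180]) and `label` (`"cis"` or `"trans"`).
#' @export
chi_rotamer <- function(snap, topo, chain, resno = NULL,
                        order = c("standard", "literal")) {
  order <- match.arg(order)
  if (is.null(resno)) resno <- prime_residue(topo, 9)
  at <- lapply(c("N", "CA", "CB", "CG"), function(a)
    .atom_xyz(snap, chain, resno, a))
  names(at) <- c("N", "CA", "CB", "CG")
  chi <- if (order == "standard") {
    dihedral_angle(at$N, at$CA, at$CB, at$CG)
  } else {
    dihedral_angle(at$CA, at$CB, at$CG, at$N)
  }
  structure(list(chi = chi, label = if (abs(chi) < 90) "cis" else "trans"),
            class = "rotamer_state")
}

#' @export
print.rotamer_state <- function(x, ...) {
  cat(sprintf("chi = %.1f deg (%s)\n", x$chi, x$label))
  invisible(x)
}
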