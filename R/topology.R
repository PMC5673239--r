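#' Receptor topology for a pentameric ligand-gated ion channel
#'
#' Describes how residue numbers map onto the architecture of a pLGIC:
#' the five subunit chains, the extracellular (EC) and transmembrane (TM)
#' residue intervals, the four TM helices, the prime-number map of the
#' pore-lining M2 helix (e.g. 9' = Leu254 in GluCl), named key residues,
#' and the cyclic subunit order that defines the principal (+) and
#' complementary (-) side of each subunit interface.
#'
#' @param chains character vector of exactly five chain identifiers, in
#'   cyclic order as seen from the extracellular side.
#' @param ec_range,tm_range inclusive residue-number intervals `c(lo, hi)`
#'   applying to every chain; they must not overlap.
#' @param m_ranges named list with elements `M1`..`M4`, each `c(lo, hi)`.
#' @param prime_map named numeric vector mapping M2 prime indices (names,
#'   e.g. `"-2"`, `"9"`, `"13"`) to residue numbers; residue number must be
#'   strictly increasing with prime index.
#' @param key_residues named numeric vector of landmark residues (e.g.
#'   `M2M3_proline = 268`, `beta12_tip = 45`, `pore_9prime = 254`). Every
#'   key residue must fall inside `ec_range` or `tm_range`.
#' @param interface_order character vector of chains defining the 5-cycle
#'   used for (+)/(-) interface pairing; defaults to `chains`.
#' @param segments optional named list of extra residue segments, e.g.
#'   `m2_sep`/`m3_sep` used by [m2_m3_separation()].
#' @return an object of class `receptor_topology`.
#' @export
receptor_topology <- function(chains, ec_range, tm_range, m_ranges,
                              prime_map, key_residues,
                              interface_order = chains, segments = list()) {
  if (length(chains) != 5 || anyDuplicated(chains)) {
    stop("configuration error in 'chains': exactly 5 distinct chain ids required")
  }
  chk_range <- function(r, what) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
      stop("configuration error in '", what, "': need c(lo, hi) with lo <= hi")
    }
    as.numeric(r)
  }
  ec_range <- chk_range(ec_range, "ec_range")
  tm_range <- chk_range(tm_range, "tm_range")
  if (ec_range[1] <= tm_range[2] && tm_range[1] <= ec_range[2]) {
    stop("configuration error: ec_range and tm_range overlap")
  }
  if (!all(c("M1", "M2", "M3", "M4") %in% names(m_ranges))) {
    stop("configuration error in 'm_ranges': need named elements M1..M4")
  }
  m_ranges <- lapply(m_ranges[c("M1", "M2", "M3", "M4")], chk_range,
                     what = "m_ranges")
  for (h in names(m_ranges)) {
    r <- m_ranges[[h]]
    if (r[1] < tm_range[1] || r[2] > tm_range[2]) {
      stop("configuration error: helix ", h, " lies outside tm_range")
    }
  }
  if (is.null(names(prime_map)) || any(names(prime_map) == "")) {
    stop("configuration error in 'prime_map': entries must be named by prime index")
  }
  pidx <- suppressWarnings(as.numeric(names(prime_map)))
  if (any(is.na(pidx))) stop("configuration error in 'prime_map': non-numeric prime index")
  o <- order(pidx)
  if (any(diff(as.numeric(prime_map)[o]) <= 0)) {
    stop("configuration error in 'prime_map': residue number must increase with prime index")
  }
  prime_map <- stats::setNames(as.numeric(prime_map)[o], names(prime_map)[o])
  if (is.null(names(key_residues)) || any(names(key_residues) == "")) {
    stop("configuration error in 'key_residues': entries must be named")
  }
  key_residues <- stats::setNames(as.numeric(key_residues), names(key_residues))
  inside <- function(r) {
    (r >= ec_range[1] & r <= ec_range[2]) | (r >= tm_range[1] & r <= tm_range[2])
  }
  bad <- names(key_residues)[!inside(key_residues)]
  if (length(bad)) {
    stop("configuration error: key residue(s) outside declared ranges: ",
         paste(bad, collapse = ", "))
  }
  if (!setequal(interface_order, chains) || length(interface_order) != 5) {
    stop("configuration error in 'interface_order': must be a permutation of chains")
  }
  segments <- lapply(segments, chk_range, what = "segments")
  structure(list(chains = as.character(chains), ec_range = ec_range,
                 tm_range = tm_range, m_ranges = m_ranges,
                 prime_map = prime_map, key_residues = key_residues,
                 interface_order = as.character(interface_order),
                 segments = segments),
            class = "receptor_topology")
}

#' @export
print.receptor_topology <- function(x, ...) {
  cat("receptor_topology: chains", paste(x$chains, collapse = ""),
      "| EC", paste(x$ec_range, collapse = "-"),
      "| TM", paste(x$tm_range, collapse = "-"), "\n")
  cat("  primes:", paste(paste0(names(x$prime_map), "'=", x$prime_map),
                         collapse = " "), "\n")
  invisible(x)
}

#' Resolve an M2 prime index to a residue number
#'
#' @param topo a [receptor_topology()].
#' @param prime prime index, numeric or character (e.g. `9` or `"9"`).
#' @return the residue number.
#' @export
prime_residue <- function(topo, prime) {
  key <- as.character(prime)
  if (!key %in% names(topo$prime_map)) {
    stop("prime index ", key, "' is not in the prime map (have: ",
         paste(names(topo$prime_map), collapse = ", "), ")")
  }
  unname(topo$prime_map[[key]])
}

#' Look up a named key residue
#' @param topo a [receptor_topology()].
#' @param name key-residue name, e.g. `"M2M3_proline"`.
#' @export
key_residue <- function(topo, name) {
  if (!name %in% names(topo$key_residues)) {
    stop("key residue '", name, "' not declared in the topology")
  }
  unname(topo$key_residues[[name]])
}

# (+)/(-) interface pairs as a data.frame(principal, complementary),
# following the declared 5-cycle.
interface_pairs <- function(topo) {
  ord <- topo$interface_order
  data.frame(principal = ord, complementary = ord[c(2:5, 1)],
             stringsAsFactors = FALSE)
}

#' Read a receptor topology from a YAML/JSON config file
#'
#' The file must declare `chains`, `ec_range`, `tm_range`, `m_ranges`
#' (map M1..M4), `prime_map`, `key_residues`, and optionally
#' `interface_order` and `segments`. Every field is validated and
#' configuration errors name the offending field.
#'
#' @param path path to the config file.
#' @return a [receptor_topology()].
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology config not found: ", path)
  cfg <- yaml::read_yaml(path)
  req <- c("chains", "ec_range", "tm_range", "m_ranges", "prime_map",
           "key_residues")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) {
    stop("configuration error: missing field(s) ", paste(miss, collapse = ", "),
         " in ", path)
  }
  receptor_topology(
    chains = unlist(cfg$chains),
    ec_range = unlist(cfg$ec_range),
    tm_range = unlist(cfg$tm_range),
    m_ranges = cfg$m_ranges,
    prime_map = unlist(cfg$prime_map),
    key_residues = unlist(cfg$key_residues),
    interface_order = unlist(cfg$interface_order) %||% unlist(cfg$chains),
    segments = cfg$segments %||% list()
  )
}
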