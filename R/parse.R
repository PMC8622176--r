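# SMILES perception layer on top of OpenBabel (via ChemmineOB).
#
# OpenBabel handles parsing, canonicalization, valence/aromaticity models and
# 2D layout; this file derives the per-atom and per-bond attributes the
# featurizer needs (Sybyl mol2 types -> hybridization/aromaticity, explicit-H
# conversion -> hydrogen counts, SDF parity -> tetrahedral chirality, bridge
# detection -> ring membership, local rules -> conjugation and cis/trans).

.ELEMENTS <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Sc = 21, Ti = 22, V = 23, Cr = 24, Mn = 25, Fe = 26,
  Co = 27, Ni = 28, Cu = 29, Zn = 30, Ga = 31, Ge = 32, As = 33, Se = 34,
  Br = 35, Kr = 36, Rb = 37, Sr = 38, Y = 39, Zr = 40, Nb = 41, Mo = 42,
  Tc = 43, Ru = 44, Rh = 45, Pd = 46, Ag = 47, Cd = 48, In = 49, Sn = 50,
  Sb = 51, Te = 52, I = 53, Xe = 54, Cs = 55, Ba = 56, La = 57, Ce = 58,
  Pr = 59, Nd = 60, Pm = 61, Sm = 62, Eu = 63, Gd = 64, Tb = 65, Dy = 66,
  Ho = 67, Er = 68, Tm = 69, Yb = 70, Lu = 71, Hf = 72, Ta = 73, W = 74,
  Re = 75, Os = 76, Ir = 77, Pt = 78, Au = 79, Hg = 80, Tl = 81, Pb = 82,
  Bi = 83, Po = 84, At = 85, Rn = 86, Fr = 87, Ra = 88, Ac = 89, Th = 90,
  Pa = 91, U = 92, Np = 93, Pu = 94, Am = 95, Cm = 96, Bk = 97, Cf = 98,
  Es = 99, Fm = 100
)

# Default valences used to estimate radical electron counts from the
# OpenBabel valence model shortfall (clamped at zero; hypervalent S/P simply
# report zero radicals).
.DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                      P = 3, S = 2, Cl = 1, Br = 1, I = 1)

.ob_convert <- function(from, to, source, opts = NULL) {
  res <- tryCatch(
    if (is.null(opts)) ChemmineOB::convertFormat(from, to, source)
    else ChemmineOB::convertFormat(from, to, source, options = opts),
    error = function(e) ""
  )
  if (is.null(res) || !nzchar(res)) "" else res
}

#' Canonical SMILES of a molecule
#'
#' @param smiles A single SMILES string.
#' @return The OpenBabel canonical SMILES, or `NA_character_` if the input
#'   does not parse.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (!nzchar(smiles)) return(NA_character_)
  out <- .ob_convert("SMI", "CAN", smiles)
  if (!nzchar(out)) return(NA_character_)
  sub("[\t\n].*$", "", out)
}

# Heavy-atom count of one SMILES fragment (implicit-H model, no H added).
.heavy_atom_count <- function(smiles) {
  sdf <- .ob_convert("SMI", "SDF", smiles)
  if (!nzchar(sdf)) return(NA_integer_)
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  if (is.na(natoms)) return(NA_integer_)
  if (natoms == 0) return(0L)
  atoms <- lines[5:(4 + natoms)]
  sym <- trimws(substr(atoms, 32, 34))
  sum(sym != "H")
}

# Counter-ion fragments removed by strip_salts(), matched by canonical
# SMILES: halide/alkali/alkaline-earth ions, ammonium, water/ammonia, and the
# common small acid counter-ions.
.SALT_SMILES <- c(
  "[Na+]", "[K+]", "[Li+]", "[Ca+2]", "[Mg+2]", "[Zn+2]", "[Ba+2]",
  "[Al+3]", "[NH4+]", "[H+]", "[OH-]", "O", "N",
  "Cl", "[Cl-]", "Br", "[Br-]", "I", "[I-]", "F", "[F-]",
  "O=[N+]([O-])O", "[O-][N+](=O)[O-]",
  "OS(=O)(=O)O", "[O-]S(=O)(=O)O", "[O-]S(=O)(=O)[O-]",
  "OP(=O)(O)O", "CS(=O)(=O)O", "Cc1ccc(cc1)S(=O)(=O)O",
  "OC(=O)C(F)(F)F"
)

.salt_env <- new.env(parent = emptyenv())

.salt_canon <- function() {
  if (is.null(.salt_env$canon)) {
    canon <- vapply(.SALT_SMILES, canonical_smiles, character(1))
    .salt_env$canon <- unique(canon[!is.na(canon)])
  }
  .salt_env$canon
}

.parse_failure <- function(smiles, msg) {
  stop(structure(
    class = c("meshgcn_parse_failure", "error", "condition"),
    list(message = sprintf("%s [smiles: %s]", msg, smiles), call = NULL)
  ))
}

#' Remove counter-ion salt fragments from a SMILES string
#'
#' Multi-fragment SMILES (fragments separated by `.`) are reduced to the drug
#' fragment by removing fragments that match a curated list of common
#' counter-ions (alkali and alkaline-earth cations, halides, ammonium,
#' water/ammonia, sulfate/nitrate/phosphate/mesylate/tosylate/
#' trifluoroacetate). A salt-free input is returned unchanged. If several
#' non-salt fragments remain, the largest (by heavy-atom count) is kept with
#' a warning; if every fragment matches the salt list, the largest fragment
#' of the input is kept so that the result is never empty.
#'
#' @param smiles A single non-empty SMILES string.
#' @return The SMILES of the desalted molecule.
#' @export
strip_salts <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(smiles)) {
    .parse_failure(if (is.character(smiles) && length(smiles) == 1) smiles
                   else "<non-string>", "empty or invalid SMILES input")
  }
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0) .parse_failure(smiles, "empty SMILES input")
  canon <- vapply(frags, canonical_smiles, character(1))
  if (anyNA(canon)) .parse_failure(smiles, "unparseable SMILES")
  if (length(frags) == 1) return(smiles)
  is_salt <- canon %in% .salt_canon()
  keep <- frags[!is_salt]
  if (length(keep) == 0) keep <- frags
  if (length(keep) > 1) {
    sizes <- vapply(keep, .heavy_atom_count, integer(1))
    if (anyNA(sizes)) .parse_failure(smiles, "unparseable SMILES fragment")
    biggest <- which.max(sizes)
    warning(sprintf(
      "multiple non-salt fragments in '%s'; keeping largest fragment '%s'",
      smiles, keep[biggest]), call. = FALSE)
    keep <- keep[biggest]
  }
  keep
}

# Parse one SMILES into atom/bond attribute tables. Returns NULL on parse
# failure. Atom order follows the SMILES heavy-atom order (OpenBabel keeps
# input order; added hydrogens are appended after the heavy atoms).
.parse_molecule <- function(smiles) {
  mol2 <- .ob_convert("SMI", "MOL2", smiles,
                      opts = data.frame(names = "h", args = ""))
  if (!nzchar(mol2)) return(NULL)
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  sec <- function(tag) which(lines == tag)
  a0 <- sec("@<TRIPOS>ATOM"); b0 <- sec("@<TRIPOS>BOND")
  if (length(a0) != 1 || length(b0) != 1) return(NULL)
  marks <- grep("^@<TRIPOS>", lines)
  next_sec <- function(i) {
    nxt <- marks[marks > i]
    if (length(nxt) == 0) length(lines) + 1L else min(nxt)
  }
  atom_lines <- lines[seq(a0 + 1, next_sec(a0) - 1)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  if (length(atom_lines) == 0) return(NULL)
  af <- strsplit(trimws(atom_lines), "[[:space:]]+")
  sybyl <- vapply(af, `[`, character(1), 6)
  element <- vapply(strsplit(sybyl, ".", fixed = TRUE), `[`, character(1), 1)
  # normalize case: mol2 name column is upper-case, sybyl keeps Cl/Br
  element <- paste0(toupper(substr(element, 1, 1)),
                    tolower(substr(element, 2, 10)))
  n_all <- length(element)
  is_h <- element == "H"

  bond_lines <- lines[seq(b0 + 1, length.out = max(0, next_sec(b0) - b0 - 1))]
  bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
  if (length(bond_lines) > 0) {
    bf <- strsplit(trimws(bond_lines), "[[:space:]]+")
    bonds_all <- data.frame(
      a1 = vapply(bf, function(x) as.integer(x[2]), integer(1)),
      a2 = vapply(bf, function(x) as.integer(x[3]), integer(1)),
      type = vapply(bf, `[`, character(1), 4),
      stringsAsFactors = FALSE
    )
  } else {
    bonds_all <- data.frame(a1 = integer(0), a2 = integer(0),
                            type = character(0), stringsAsFactors = FALSE)
  }

  # formal charges from the UNITY_ATOM_ATTR block
  charge <- integer(n_all)
  u0 <- sec("@<TRIPOS>UNITY_ATOM_ATTR")
  if (length(u0) == 1) {
    i <- u0 + 1
    stop_at <- next_sec(u0)
    while (i < stop_at) {
      hdr <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
      if (length(hdr) < 2) break
      idx <- as.integer(hdr[1]); nattr <- as.integer(hdr[2])
      for (j in seq_len(nattr)) {
        kv <- strsplit(trimws(lines[i + j]), "[[:space:]]+")[[1]]
        if (identical(kv[1], "charge")) charge[idx] <- as.integer(kv[2])
      }
      i <- i + nattr + 1
    }
  }

  heavy_idx <- which(!is_h)
  n_heavy <- length(heavy_idx)
  if (n_heavy == 0) return(NULL)
  remap <- integer(n_all); remap[heavy_idx] <- seq_len(n_heavy)

  h_per_atom <- integer(n_heavy)
  heavy_bonds <- bonds_all[0, ]
  if (nrow(bonds_all) > 0) {
    bh1 <- is_h[bonds_all$a1]; bh2 <- is_h[bonds_all$a2]
    hb <- bonds_all[bh1 | bh2, , drop = FALSE]
    if (nrow(hb) > 0) {
      heavy_end <- ifelse(is_h[hb$a1], hb$a2, hb$a1)
      heavy_end <- heavy_end[!is_h[heavy_end]]
      tab <- table(remap[heavy_end])
      h_per_atom[as.integer(names(tab))] <- as.integer(tab)
    }
    heavy_bonds <- bonds_all[!bh1 & !bh2, , drop = FALSE]
    heavy_bonds$a1 <- remap[heavy_bonds$a1]
    heavy_bonds$a2 <- remap[heavy_bonds$a2]
  }

  degree <- integer(n_heavy)
  if (nrow(heavy_bonds) > 0) {
    tab <- table(c(heavy_bonds$a1, heavy_bonds$a2))
    degree[as.integer(names(tab))] <- as.integer(tab)
  }

  # ring membership: a bond is in a ring iff it is not a bridge
  bond_in_ring <- rep(FALSE, nrow(heavy_bonds))
  atom_in_ring <- rep(FALSE, n_heavy)
  if (nrow(heavy_bonds) > 0) {
    g <- igraph::graph_from_edgelist(
      cbind(heavy_bonds$a1, heavy_bonds$a2), directed = FALSE)
    if (igraph::vcount(g) < n_heavy) {
      g <- igraph::add_vertices(g, n_heavy - igraph::vcount(g))
    }
    br <- igraph::bridges(g)
    bond_in_ring <- !(seq_len(nrow(heavy_bonds)) %in% as.integer(br))
    ring_atoms <- unique(c(heavy_bonds$a1[bond_in_ring],
                           heavy_bonds$a2[bond_in_ring]))
    atom_in_ring[ring_atoms] <- TRUE
  }

  bond_aromatic <- heavy_bonds$type == "ar"
  atom_aromatic <- rep(FALSE, n_heavy)
  if (any(bond_aromatic)) {
    aidx <- unique(c(heavy_bonds$a1[bond_aromatic],
                     heavy_bonds$a2[bond_aromatic]))
    atom_aromatic[aidx] <- TRUE
  }
  atom_aromatic <- atom_aromatic | grepl("\\.ar$", sybyl[heavy_idx])

  hyb <- vapply(sybyl[heavy_idx], function(s) {
    suf <- sub("^[^.]+\\.?", "", s)
    switch(suf,
           "1" = "SP", "2" = "SP2", "3" = "SP3",
           "ar" = "SP2", "co2" = "SP2", "am" = "SP2", "pl3" = "SP2",
           "o" = "SP3", "o2" = "SP3", "th" = "SP3", "t" = "SP",
           "")
  }, character(1))
  hvy_el <- element[heavy_idx]
  hyb[hyb == ""] <- ifelse(degree[hyb == ""] >= 1, "SP3", "S")

  atomic_num <- unname(.ELEMENTS[hvy_el])
  atomic_num[is.na(atomic_num)] <- 0L  # maps to the "other" bucket

  # bond order sum (aromatic counted 1.5) for the radical estimate
  order_num <- function(t) switch(t, "1" = 1, "2" = 2, "3" = 3,
                                  "am" = 1, "ar" = 1.5, 1)
  bsum <- numeric(n_heavy)
  if (nrow(heavy_bonds) > 0) {
    bo <- vapply(heavy_bonds$type, order_num, numeric(1))
    for (k in seq_len(nrow(heavy_bonds))) {
      bsum[heavy_bonds$a1[k]] <- bsum[heavy_bonds$a1[k]] + bo[k]
      bsum[heavy_bonds$a2[k]] <- bsum[heavy_bonds$a2[k]] + bo[k]
    }
  }
  hcharge <- charge[heavy_idx]
  expval <- unname(.DEFAULT_VALENCE[hvy_el])
  # charge shifts the expected valence for the common hetero-elements
  expval <- ifelse(hvy_el %in% c("N", "P"), expval + hcharge,
            ifelse(hvy_el %in% c("O", "S"), expval + hcharge, expval))
  radicals <- pmax(0, round(expval - bsum - h_per_atom))
  radicals[is.na(radicals)] <- 0

  # tetrahedral parity from the SDF atom block (0 none, 1 cw, 2 ccw)
  chirality <- rep("none", n_heavy)
  coords <- NULL
  sdf <- .ob_convert("SMI", "SDF", smiles)
  if (nzchar(sdf)) {
    sl <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
    natoms <- suppressWarnings(as.integer(substr(sl[4], 1, 3)))
    if (!is.na(natoms) && natoms >= n_heavy) {
      al <- sl[5:(4 + natoms)]
      fields <- strsplit(trimws(al), "[[:space:]]+")
      sdf_sym <- vapply(fields, `[`, character(1), 4)
      sdf_heavy <- which(sdf_sym != "H")[seq_len(n_heavy)]
      par <- vapply(fields[sdf_heavy], function(x) {
        p <- suppressWarnings(as.integer(x[7]))
        if (is.na(p)) 0L else p
      }, integer(1))
      chirality <- c("none", "cw", "ccw", "other")[pmin(par, 3L) + 1L]
      coords <- cbind(
        x = vapply(fields[sdf_heavy], function(x) as.numeric(x[1]), numeric(1)),
        y = vapply(fields[sdf_heavy], function(x) as.numeric(x[2]), numeric(1)))
    }
  }

  bond_type <- vapply(heavy_bonds$type, function(t) {
    switch(t, "1" = "single", "2" = "double", "3" = "triple",
           "ar" = "aromatic", "am" = "single", "other")
  }, character(1))

  # conjugation: aromatic bonds; multiple bonds adjacent to another multiple
  # bond; single bonds whose two ends are each pi-capable (another multiple
  # bond, or an N/O/S lone pair) with at least one true multiple-bond end
  conj <- rep(FALSE, nrow(heavy_bonds))
  if (nrow(heavy_bonds) > 0) {
    multiple <- bond_type %in% c("double", "triple", "aromatic")
    has_other_multiple <- function(atom, bond_k) {
      inc <- which((heavy_bonds$a1 == atom | heavy_bonds$a2 == atom) &
                     seq_len(nrow(heavy_bonds)) != bond_k)
      any(multiple[inc])
    }
    lp <- hvy_el %in% c("N", "O", "S")
    for (k in seq_len(nrow(heavy_bonds))) {
      u <- heavy_bonds$a1[k]; v <- heavy_bonds$a2[k]
      if (bond_type[k] == "aromatic") {
        conj[k] <- TRUE
      } else if (multiple[k]) {
        conj[k] <- has_other_multiple(u, k) || has_other_multiple(v, k)
      } else {
        mu <- has_other_multiple(u, k); mv <- has_other_multiple(v, k)
        conj[k] <- (mu || lp[u]) && (mv || lp[v]) && (mu || mv)
      }
    }
  }

  stereo <- rep("none", nrow(heavy_bonds))
  if (grepl("[/\\\\]", smiles) && !is.null(coords) && nrow(heavy_bonds) > 0) {
    stereo <- .classify_cis_trans(heavy_bonds, bond_type, bond_in_ring,
                                  degree, coords)
  }

  atoms <- data.frame(
    element = hvy_el, atomic_num = atomic_num, chirality = chirality,
    degree = degree, formal_charge = hcharge, n_hs = h_per_atom,
    n_radicals = radicals, hybridization = hyb,
    aromatic = atom_aromatic, in_ring = atom_in_ring,
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(
    a1 = heavy_bonds$a1, a2 = heavy_bonds$a2, bond_type = bond_type,
    stereo = stereo, conjugated = conj, stringsAsFactors = FALSE
  )
  list(atoms = atoms, bonds = bonds, n_heavy = n_heavy)
}

# Classify acyclic double bonds as cis/trans from the 2D depiction: the
# reference substituent on each end is the lowest-index heavy neighbour;
# same side of the double-bond axis -> cis. Only called when the source
# SMILES carries directional bond markers.
.classify_cis_trans <- function(bonds, bond_type, bond_in_ring, degree,
                                coords) {
  stereo <- rep("none", nrow(bonds))
  dbl <- which(bond_type == "double" & !bond_in_ring)
  for (k in dbl) {
    u <- bonds$a1[k]; v <- bonds$a2[k]
    nb <- function(a, other) {
      inc <- c(bonds$a2[bonds$a1 == a], bonds$a1[bonds$a2 == a])
      sort(setdiff(inc, other))
    }
    su <- nb(u, v); sv <- nb(v, u)
    if (length(su) == 0 || length(sv) == 0) next
    p_u <- coords[u, ]; p_v <- coords[v, ]
    axis <- p_v - p_u
    side <- function(p) sign(axis[1] * (p[2] - p_u[2]) -
                               axis[2] * (p[1] - p_u[1]))
    s1 <- side(coords[su[1], ]); s2 <- side(coords[sv[1], ])
    if (s1 == 0 || s2 == 0) next
    stereo[k] <- if (s1 == s2) "cis" else "trans"
  }
  stereo
}
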