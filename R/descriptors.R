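# Featurization: the fixed, ordered 1D/2D descriptor vector.
#
# The descriptor set is pinned by descriptor_config(): a versioned, ordered
# list of 207 names computed from OpenBabel molecular properties, elemental
# and bond composition, ring statistics, and a curated table of SMARTS
# substructure counts. The order is fixed across an entire run; identical
# canonical structures yield identical vectors.

DESCRIPTOR_CONFIG_VERSION <- "qsarpipe-207-v1"

# SMARTS substructure-count table. Counts are unique atom-set matches.
descriptor_smarts <- function() {
  p <- c(
    # carbon environments
    nCsp3_H3 = "[CX4H3]", nCsp3_H2 = "[CX4H2]", nCsp3_H1 = "[CX4H1]",
    nCsp3_H0 = "[CX4H0]", nCsp2 = "[CX3]", nCsp = "[CX2]",
    nArC_H = "[cH]", nArC_sub = "[cH0]", nC_ring = "[C;R]",
    nC_acyclic = "[C;!R]", nArC = "[c]",
    nC_allylic = "[CX4][CX3]=[CX3]", nC_benzylic = "[CX4]c",
    # nitrogen environments
    nN_prim_amine = "[NX3H2;!$(NC=O)]", nN_sec_amine = "[NX3H1;!$(NC=O)]",
    nN_tert_amine = "[NX3H0;!$(NC=O);!$(N=O)]",
    nN_sp2 = "[NX2]", nN_sp = "[NX1]", nArN = "[n]", nArN_H = "[nH]",
    nArN_noH = "[nH0]", nN_ring = "[N;R]", nN_acyclic = "[N;!R]",
    nN_positive = "[#7+]", nN_aniline = "[NX3;$(Nc)]",
    # oxygen environments
    nO_OH = "[OX2H]", nO_sub = "[OX2H0]", nO_carbonyl = "[OX1]",
    nArO = "[o]", nO_ring = "[O;R]", nO_acyclic = "[O;!R]",
    nO_phenol = "[OX2H;$(Oc)]", nO_aliph_OH = "[OX2H;$(O[CX4])]",
    # sulfur / phosphorus
    nS_sulfide = "[SX2]", nS_SH = "[SX2H]", nS_sulfoxide = "[SX3]",
    nS_sulfonyl = "[SX4]", nArS = "[s]", nS_ring = "[S;R]",
    nP_any = "[#15]", nP_oxide = "[PX4]",
    # halogen environments
    nF_arom = "[F;$(Fc)]", nF_aliph = "[F;$(FC)]",
    nCl_arom = "[Cl;$(Clc)]", nCl_aliph = "[Cl;$(ClC)]",
    nBr_arom = "[Br;$(Brc)]", nBr_aliph = "[Br;$(BrC)]",
    nI_arom = "[I;$(Ic)]", nI_aliph = "[I;$(IC)]",
    # functional groups
    fgCarbonyl = "[CX3]=[OX1]", fgAldehyde = "[CX3H1](=O)[#6]",
    fgKetone = "[#6][CX3](=O)[#6]", fgCarboxylicAcid = "[CX3](=O)[OX2H1]",
    fgEster = "[#6][CX3](=O)[OX2H0][#6]", fgAmide = "[NX3][CX3](=[OX1])",
    fgAmidePrimary = "[NX3H2][CX3](=[OX1])",
    fgUrea = "[NX3][CX3](=[OX1])[NX3]",
    fgCarbamate = "[NX3][CX3](=[OX1])[OX2]",
    fgAnhydride = "[CX3](=O)[OX2][CX3](=O)",
    fgAcylHalide = "[CX3](=O)[F,Cl,Br,I]",
    fgNitrile = "[NX1]#[CX2]",
    fgNitro = "[$([NX3](=O)=O),$([NX3+](=O)[O-])]",
    fgNitroso = "[NX2]=[OX1]", fgAzo = "[NX2]=[NX2]",
    fgHydrazine = "[NX3][NX3]", fgHydroxylamine = "[NX3][OX2H]",
    fgOxime = "[CX3]=[NX2][OX2H]", fgImine = "[CX3]=[NX2]",
    fgAmidine = "[NX3][CX3]=[NX2]",
    fgGuanidine = "[NX3][CX3](=[NX2])[NX3]",
    fgEtherDialkyl = "[OD2]([CX4])[CX4]", fgEtherAromatic = "[OD2](c)[#6]",
    fgMethoxy = "[OX2][CH3]", fgThioether = "[SD2]([#6])[#6]",
    fgDisulfide = "[SX2][SX2]", fgThione = "[CX3]=[SX1]",
    fgSulfoxide = "[SX3](=[OX1])", fgSulfone = "[SX4](=[OX1])(=[OX1])",
    fgSulfonamide = "[SX4](=[OX1])(=[OX1])[NX3]",
    fgSulfonicAcid = "[SX4](=[OX1])(=[OX1])[OX2H]",
    fgPhosphoryl = "[PX4](=[OX1])", fgAlcohol = "[CX4][OX2H]",
    fgEnol = "[CX3]=[CX3][OX2H]", fgQuaternaryN = "[NX4+]",
    fgAlkylHalide = "[CX4][F,Cl,Br,I]", fgCF3 = "[CX4](F)(F)F",
    fgAlkene = "[CX3]=[CX3]", fgAlkyne = "[CX2]#[CX2]",
    fgEnone = "[CX3]=[CX3][CX3]=[OX1]", fgEpoxide = "[OX2r3]",
    fgAziridine = "[NX3r3]", fgLactone = "[C;R](=O)[O;R]",
    fgLactam = "[C;R](=O)[N;R]", fgArylCarbonyl = "c[CX3]=[OX1]",
    fgNMethyl = "[NX3][CH3]", fgGemDimethyl = "[CX4]([CH3])[CH3]",
    fgIsopropyl = "[CX4H1]([CH3])[CH3]",
    fgTertButyl = "[CX4]([CH3])([CH3])[CH3]",
    fgVinyl = "[CX3H2]=[CX3]", fgBenzylCH2 = "[CH2]c",
    fgAcetyl = "[CH3][CX3]=[OX1]",
    # aromatic systems and ring environments
    arBenzene = "c1ccccc1", arPyridine = "c1ccncc1",
    arPyrimidineLike = "c1cncnc1", arNaphthalene = "c1ccc2ccccc2c1",
    arAtoms5Ring = "[a;r5]", arAtoms6Ring = "[a;r6]",
    arBiarylBond = "c-!@c", nFusedRingAtoms = "[R2]",
    nSingleRingAtoms = "[R1]", nRing3Atoms = "[R3]",
    arFuranO = "[o;r5]", arThiopheneS = "[s;r5]",
    arPyrroleNH = "[nH;r5]", arN5Ring = "[n;r5]",
    nRingNH = "[NH1;R]", nRingCarbonyl = "[C;R]=[OX1]",
    # topological pairs and paths
    pathCCC = "[CH2][CH2][CH2]", pathCC = "[CX4][CX4]",
    pairCN = "[#6]~[#7]", pairCO = "[#6]~[#8]", pairCS = "[#6]~[#16]",
    pairNO = "[#7]~[#8]", pairHeteroHetero = "[!#6;!#1]~[!#6;!#1]",
    pairCHalogen = "[#6][F,Cl,Br,I]",
    pathOCCO = "[OX2][CH2][CH2][OX2]", pathNCCN = "[NX3][CH2][CH2][NX3]",
    pathNCCO = "[NX3][CH2][CH2][OX2]",
    pathChain4 = "[CH2][CH2][CH2][CH2]",
    nBranch3 = "[CX4]([#6])([#6])[#6]",
    nBranch4 = "[CX4]([#6])([#6])([#6])[#6]",
    nTermMethyl = "[CH3]", nMethylOnN = "[CH3][#7]", nMethylOnO = "[CH3][#8]",
    nPolarH = "[$([!#6;!#1;!H0])]",
    nAcceptorNO = "[$([#7;H0]),$([#8;H0])]",
    nDonorNO = "[$([#7;!H0]),$([#8;!H0])]",
    # aryl attachments, degrees and miscellaneous environments
    arAttachN = "c[NX3]", arAttachO = "c[OX2]", arAttachS = "c[SX2]",
    arAttachHalogen = "c[F,Cl,Br,I]", arAttachCsp3 = "c[CX4]",
    arRingJunction = "[c;R2]",
    nDeg1 = "[D1]", nDeg2 = "[D2]", nDeg3 = "[D3]", nDeg4 = "[D4]",
    nHeteroInRing = "[!#6;!#1;R]", nHeteroAcyclic = "[!#6;!#1;!R]",
    nAnion = "[*-]", nCation = "[*+]",
    fgAmideNH = "[NX3H1][CX3]=[OX1]", nNsp3Ring = "[NX3;R]",
    nOsp3Ring = "[OX2;R]", nArCH2Bridge = "c[CX4]c",
    nCarbonylIn6Ring = "[C;r6]=[OX1]",
    nCH2BetweenHetero = "[!#6;!#1][CH2][!#6;!#1]",
    nQuatRingC = "[CX4H0;R]"
  )
  data.frame(name = names(p), pattern = unname(p), stringsAsFactors = FALSE)
}

# Bond-class counts, computed as unique SMARTS bond matches.
BOND_SMARTS <- c(
  nBonds = "*~*", nSingleBonds = "*-*", nDoubleBonds = "*=*",
  nTripleBonds = "*#*", nAromaticBonds = "*:*", nRingBonds = "*@*",
  ROTB = "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"
)

ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si", "Se")

#' The pinned descriptor configuration
#'
#' Returns the versioned, ordered descriptor name list (207 descriptors by
#' default) used as the model input representation, plus the SMARTS table
#' backing the substructure-count block. The same configuration object must
#' be used for training, holdout and prediction calls within a run; the
#' descriptor-name hash is embedded in every feature matrix for that check.
#'
#' @param names optional character vector to restrict/reorder the descriptor
#'   set (a config override; the default is the full pinned list).
#' @return List with `names` (ordered descriptor identifiers), `version`,
#'   and `hash` (of the name list).
#' @export
#' @examples
#' length(descriptor_config()$names)  # 207
descriptor_config <- function(names = NULL) {
  sm <- descriptor_smarts()
  full <- c(
    # OpenBabel molecular properties
    "MW", "AlogP", "TPSA", "MR", "HBA_Lipinski", "HBA", "HBD",
    # elemental composition
    paste0("n", ELEMENTS), "nHeavy", "nHetero", "fracHetero", "nH",
    # bond statistics
    names(BOND_SMARTS), "fracRotatable",
    # ring statistics
    "nRings", "nAromaticRings", "nAliphaticRings", "nRingAtoms",
    "fracRingAtoms", "maxRingSize", "minRingSize",
    paste0("nRingsSize", 3:8),
    # simple derived ratios
    "MWperHeavy", "TPSAperHeavy", "polarAtomFrac", "HBtotal", "nHalogen",
    # substructure counts
    sm$name
  )
  sel <- names %||% full
  if (!all(sel %in% full))
    stopf("descriptor_config: unknown descriptor name(s): %s",
          paste(setdiff(sel, full), collapse = ", "))
  list(names = sel, version = DESCRIPTOR_CONFIG_VERSION,
       hash = descriptor_hash(sel), smarts = sm)
}

descriptor_hash <- function(names) {
  # dependency-free stable hash of the ordered name list
  s <- paste(names, collapse = "|")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2147483647
  sprintf("%s-%d-%d", DESCRIPTOR_CONFIG_VERSION, length(names), h)
}

#' Featurize molecules into the fixed descriptor matrix
#'
#' Computes the ordered 1D/2D descriptor vector for each molecule. All
#' OpenBabel work is batched: one SMILES parse, one molecular-property pass
#' and one pass per SMARTS pattern. Non-finite descriptor values are set to
#' `NA` (to be imputed from training statistics via [fit_imputer()]);
#' molecules with more than `max_na_frac` non-finite descriptors are
#' excluded and logged.
#'
#' @param smiles character vector of valid (canonical) SMILES.
#' @param ids molecule identifiers (rownames of the result).
#' @param config descriptor configuration from [descriptor_config()].
#' @param max_na_frac exclusion threshold on the per-molecule fraction of
#'   non-finite descriptors (default 0.2).
#' @return List with `matrix` (molecules x descriptors, rownames = ids,
#'   attribute `descriptor_hash`), and `excluded` (data.frame of dropped
#'   molecules with reasons).
#' @export
featurize <- function(smiles, ids = NULL, config = descriptor_config(),
                      max_na_frac = 0.2) {
  if (!length(smiles)) stopf("featurize: no molecules")
  ids <- ids %||% sprintf("m%06d", seq_along(smiles))
  if (anyDuplicated(ids)) stopf("featurize: duplicate molecule ids")
  sdf <- smiles_to_sdfset(smiles, ids)
  ob <- ChemmineR:::obmol(sdf)
  n <- length(smiles)

  props <- ChemmineOB::prop_OB(ob)
  vals <- list()
  vals$MW <- props$MW; vals$AlogP <- props$logP; vals$TPSA <- props$TPSA
  vals$MR <- props$MR; vals$HBA_Lipinski <- props$HBA1; vals$HBA <- props$HBA2
  vals$HBD <- props$HBD

  # elemental composition from the atom block
  am <- ChemmineR::atomcountMA(sdf, addH = FALSE)
  if (is.null(dim(am))) am <- matrix(am, nrow = 1, dimnames = list(NULL, names(am)))
  for (el in ELEMENTS) {
    vals[[paste0("n", el)]] <-
      if (el %in% colnames(am)) unname(am[, el]) else rep(0, n)
  }
  nheavy <- rowSums(am)
  ncarbon <- vals$nC
  vals$nHeavy <- nheavy
  vals$nHetero <- nheavy - ncarbon
  vals$fracHetero <- ifelse(nheavy > 0, (nheavy - ncarbon) / nheavy, 0)
  vals$nH <- formula_h_count(props$formula)

  # bond statistics (unique SMARTS bond matches)
  for (nm in names(BOND_SMARTS)) {
    vals[[nm]] <- unname(ChemmineOB::smartsSearch_OB(ob, BOND_SMARTS[[nm]],
                                                     uniqueMatches = TRUE))
  }
  vals$fracRotatable <- ifelse(vals$nBonds > 0, vals$ROTB / vals$nBonds, 0)

  # ring statistics
  ri <- ring_stats(sdf, nheavy)
  for (nm in names(ri)) vals[[nm]] <- ri[[nm]]

  vals$MWperHeavy <- ifelse(nheavy > 0, vals$MW / nheavy, 0)
  vals$TPSAperHeavy <- ifelse(nheavy > 0, vals$TPSA / nheavy, 0)
  vals$polarAtomFrac <- ifelse(nheavy > 0, (vals$nN + vals$nO) / nheavy, 0)
  vals$HBtotal <- vals$HBA + vals$HBD
  vals$nHalogen <- vals$nF + vals$nCl + vals$nBr + vals$nI

  sm <- config$smarts %||% descriptor_smarts()
  want <- intersect(config$names, sm$name)
  for (nm in want) {
    pat <- sm$pattern[match(nm, sm$name)]
    vals[[nm]] <- unname(ChemmineOB::smartsSearch_OB(ob, pat,
                                                     uniqueMatches = TRUE))
  }

  missing <- setdiff(config$names, names(vals))
  if (length(missing))
    stopf("featurize: descriptors not computed: %s", paste(missing, collapse = ", "))
  X <- do.call(cbind, vals[config$names])
  colnames(X) <- config$names
  rownames(X) <- ids
  X[!is.finite(X)] <- NA_real_

  na_frac <- rowMeans(is.na(X))
  drop <- na_frac > max_na_frac
  excluded <- data.frame(mol_id = ids[drop],
                         reason = sprintf("%.0f%% of descriptors non-finite",
                                          100 * na_frac[drop]),
                         stringsAsFactors = FALSE)
  X <- X[!drop, , drop = FALSE]
  attr(X, "descriptor_hash") <- config$hash
  list(matrix = X, excluded = excluded)
}

formula_h_count <- function(formula) {
  m <- regmatches(formula, regexec("H([0-9]*)([A-Z]|$)", formula))
  vapply(m, function(x) {
    if (length(x) < 2L || !nzchar(x[1])) return(0)
    if (!nzchar(x[2])) 1 else as.numeric(x[2])
  }, 0.0)
}

ring_stats <- function(sdf, nheavy) {
  rr <- ChemmineR::rings(sdf, type = "all", arom = TRUE, inner = FALSE)
  n <- length(sdf)
  out <- list(nRings = numeric(n), nAromaticRings = numeric(n),
              nAliphaticRings = numeric(n), nRingAtoms = numeric(n),
              fracRingAtoms = numeric(n), maxRingSize = numeric(n),
              minRingSize = numeric(n))
  for (s in 3:8) out[[paste0("nRingsSize", s)]] <- numeric(n)
  for (i in seq_len(n)) {
    ringsets <- rr[[i]]$RINGS
    if (!length(ringsets)) next
    sizes <- lengths(ringsets)
    arom <- rr[[i]]$AROMATIC
    out$nRings[i] <- length(ringsets)
    out$nAromaticRings[i] <- sum(arom)
    out$nAliphaticRings[i] <- sum(!arom)
    atoms <- unique(unlist(ringsets))
    out$nRingAtoms[i] <- length(atoms)
    out$fracRingAtoms[i] <- length(atoms) / max(nheavy[i], 1)
    out$maxRingSize[i] <- max(sizes)
    out$minRingSize[i] <- min(sizes)
    for (s in 3:8) out[[paste0("nRingsSize", s)]][i] <- sum(sizes == s)
  }
  out
}

#' Impute missing descriptor values from training statistics
#'
#' `fit_imputer()` records the per-descriptor training-set medians;
#' `apply_imputer()` fills `NA` cells with those frozen medians, so that
#' prediction-time molecules are treated exactly as training-time ones.
#'
#' @param X training feature matrix (may contain `NA`).
#' @return `fit_imputer`: an imputer object (named medians).
#' @export
fit_imputer <- function(X) {
  med <- apply(X, 2, function(col) {
    m <- stats::median(col, na.rm = TRUE)
    if (!is.finite(m)) 0 else m
  })
  structure(list(medians = med), class = "qsar_imputer")
}

#' @rdname fit_imputer
#' @param imputer object from `fit_imputer()`.
#' @export
apply_imputer <- function(imputer, X) {
  stopifnot(inherits(imputer, "qsar_imputer"))
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- imputer$medians[[colnames(X)[j]]]
  }
  X
}

#' Z-score standardizer with frozen statistics
#'
#' Fits per-descriptor mean/sd on a reference pool and applies the frozen
#' transform elsewhere. Zero-variance descriptors get sd 1 (they standardize
#' to 0). Used for nearest-neighbor distances and scale-sensitive learners;
#' tree ensembles consume raw descriptors.
#'
#' @param X numeric matrix.
#' @return `fit_standardizer`: a standardizer object.
#' @export
fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  structure(list(mean = mu, sd = sdv), class = "qsar_standardizer")
}

#' @rdname fit_standardizer
#' @param standardizer object from `fit_standardizer()`.
#' @export
apply_standardizer <- function(standardizer, X) {
  stopifnot(inherits(standardizer, "qsar_standardizer"))
  sweep(sweep(X, 2, standardizer$mean, "-"), 2, standardizer$sd, "/")
}

#' Six calculated physicochemical properties
#'
#' Computes the structure-derived physicochemical profile: molecular weight
#' (g/mol), topological polar surface area (A^2), hydrogen-bond acceptor and
#' donor counts, rotatable bonds (single, non-ring, non-terminal bonds), and
#' AlogP (atom-contribution octanol/water partition coefficient).
#'
#' @param smiles character vector of valid SMILES.
#' @param ids optional molecule identifiers.
#' @return data.frame with columns `mol_id`, `MW`, `PSA`, `HBA`, `HBD`,
#'   `ROTB`, `AlogP`.
#' @export
#' @examples
#' physchem("c1ccccc1")  # benzene: MW 78.11, PSA 0, no donors/acceptors
physchem <- function(smiles, ids = NULL) {
  ids <- ids %||% sprintf("m%06d", seq_along(smiles))
  sdf <- smiles_to_sdfset(smiles, ids)
  ob <- ChemmineR:::obmol(sdf)
  props <- ChemmineOB::prop_OB(ob)
  rotb <- ChemmineOB::smartsSearch_OB(ob, BOND_SMARTS[["ROTB"]],
                                      uniqueMatches = TRUE)
  data.frame(mol_id = ids, MW = props$MW, PSA = props$TPSA, HBA = props$HBA2,
             HBD = props$HBD, ROTB = as.numeric(rotb), AlogP = props$logP,
             stringsAsFactors = FALSE)
}
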