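#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical SMILES and derives the structure
#' key used for deduplication (identical structures yield identical keys,
#' whatever the input atom ordering). Unparseable SMILES are not fatal: they
#' are returned as rejected rows so a pipeline can log and skip them.
#'
#' @param smiles character vector of SMILES strings.
#' @return A data.frame with one row per input: `smiles` (the input),
#'   `canonical` (canonical SMILES or `NA` on failure), `structure_key`
#'   (identical for identical structures; `NA` on failure), `ok` (logical),
#'   `reason` (skip reason for failures, `""` otherwise).
#' @export
#' @examples
#' canonicalize_smiles(c("OCC", "CCO", "C1CC"))
canonicalize_smiles <- function(smiles) {
  if (!length(smiles)) stopf("canonicalize_smiles: empty input")
  if (!is.character(smiles) || any(is.na(smiles)) || any(!nzchar(smiles)))
    stopf("canonicalize_smiles: SMILES must be non-empty strings")
  tag <- sprintf("q%08d", seq_along(smiles))
  res <- data.frame(smiles = smiles, canonical = NA_character_,
                    structure_key = NA_character_, ok = FALSE,
                    reason = "unparseable SMILES", stringsAsFactors = FALSE)
  convert_batch <- function(idx) {
    txt <- paste(paste(smiles[idx], tag[idx]), collapse = "\n")
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", txt)),
      error = function(e) "")
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    can <- vapply(parts, `[`, "", 1L)
    ttl <- trimws(vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", ""))
    hit <- match(tag[idx], ttl)
    found <- !is.na(hit) & nzchar(can[ifelse(is.na(hit), 1L, hit)])
    ok_idx <- idx[found]
    res$canonical[ok_idx] <<- can[hit[found]]
    res$structure_key[ok_idx] <<- can[hit[found]]
    res$ok[ok_idx] <<- TRUE
    res$reason[ok_idx] <<- ""
    idx[!found]
  }
  # OpenBabel stops reading a SMILES stream at the first malformed record,
  # so molecules after a bad one come back missing: retry those one by one
  # to separate genuinely unparseable inputs from collateral drops.
  missing <- convert_batch(seq_along(smiles))
  for (i in missing) convert_batch(i)
  res
}

#' Build molecule records from a raw table
#'
#' Canonicalizes SMILES, attaches the drug flag and ATC codes, and drops
#' (with a machine-readable skip log) molecules whose SMILES fail to parse.
#' One row per input `mol_id`; deduplication by structure key happens later,
#' at curation time.
#'
#' @param df data.frame with columns `mol_id`, `smiles`, and optionally
#'   `is_drug` (logical or 0/1) and `atc_codes` (semicolon-separated string).
#' @return List with `records` (data.frame: `mol_id`, `smiles` (canonical),
#'   `structure_key`, `is_drug`, `atc_codes`) and `skipped` (data.frame of
#'   rejected rows with reasons).
#' @export
molecule_records <- function(df) {
  need <- c("mol_id", "smiles")
  if (!all(need %in% names(df)))
    stopf("molecule_records: missing columns: %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[!duplicated(df$mol_id), , drop = FALSE]
  can <- canonicalize_smiles(df$smiles)
  is_drug <- if ("is_drug" %in% names(df)) as.logical(df$is_drug) else rep(FALSE, nrow(df))
  atc <- if ("atc_codes" %in% names(df)) as.character(df$atc_codes) else rep("", nrow(df))
  atc[is.na(atc)] <- ""
  rec <- data.frame(mol_id = as.character(df$mol_id),
                    smiles = can$canonical,
                    structure_key = can$structure_key,
                    is_drug = is_drug, atc_codes = atc,
                    stringsAsFactors = FALSE)
  skipped <- data.frame(mol_id = rec$mol_id[!can$ok],
                        smiles = df$smiles[!can$ok],
                        reason = can$reason[!can$ok], stringsAsFactors = FALSE)
  list(records = rec[can$ok, , drop = FALSE], skipped = skipped)
}

# Parse a character vector of valid SMILES into an SDFset with ids as cids.
# Assumes canonicalized, parseable input (canonicalize_smiles upstream).
smiles_to_sdfset <- function(smiles, ids = NULL) {
  ids <- ids %||% sprintf("m%06d", seq_along(smiles))
  x <- smiles
  names(x) <- ids
  suppressWarnings(ChemmineR::smiles2sdf(x))
}

#' Murcko scaffold keys
#'
#' Computes the canonical key of each molecule's Murcko framework: the ring
#' systems plus the linkers connecting them, with all side chains removed.
#' Implemented by iteratively pruning terminal heavy atoms from the
#' molecular graph; the retained substructure is canonicalized with
#' OpenBabel. Acyclic molecules have no framework and map to the designated
#' empty key `""`.
#'
#' @param smiles character vector of valid SMILES.
#' @return character vector of scaffold keys, `""` for acyclic molecules.
#' @export
#' @examples
#' murcko_scaffold(c("Cc1ccccc1", "c1ccccc1", "CCC"))
murcko_scaffold <- function(smiles) {
  if (!length(smiles)) return(character(0))
  sdf <- smiles_to_sdfset(smiles)
  n <- length(sdf)
  blocks <- character(n)
  for (i in seq_len(n)) {
    mol <- sdf[[i]]
    keep <- murcko_keep_atoms(mol)
    if (length(keep) < 3L) next  # smallest ring has 3 atoms; else acyclic
    sub <- ChemmineR::atomsubset(mol, keep)
    blocks[i] <- paste(ChemmineR::sdf2str(sub), collapse = "\n")
  }
  keys <- rep("", n)
  cyc <- which(nzchar(blocks))
  if (length(cyc)) {
    txt <- paste(blocks[cyc], collapse = "\n")
    out <- suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", txt))
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    can <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
    if (length(can) != length(cyc))
      stopf("murcko_scaffold: scaffold canonicalization lost molecules")
    keys[cyc] <- can
  }
  keys
}

# Indices of atoms retained in the Murcko framework: iteratively delete
# atoms of heavy-atom degree <= 1 until only rings and linkers remain.
murcko_keep_atoms <- function(mol) {
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  n <- nrow(ab)
  if (is.null(bb) || nrow(bb) == 0L) return(integer(0))
  e1 <- as.integer(bb[, 1]); e2 <- as.integer(bb[, 2])
  keep <- rep(TRUE, n)
  repeat {
    live <- keep[e1] & keep[e2]
    deg <- tabulate(c(e1[live], e2[live]), n)
    term <- which(keep & deg <= 1L)
    if (!length(term)) break
    keep[term] <- FALSE
  }
  which(keep)
}
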