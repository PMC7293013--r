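# Experimental measurements: parsing, validation, and binding of atom
# selectors to ensemble topology indices.
#
# A measurement table is a TSV/CSV with header and '#' comments, columns:
#   id, class, resid1, atom1, resid2, atom2,
#   [resid3, atom3, resid4, atom4 | torsion_name],
#   value, sigma, sense, dataset, coupling_type
# class is one of noe_distance (value in Angstrom), scalar_coupling (Hz),
# rdc (Hz).  sense is equality, upper_bound or lower_bound.

MEASUREMENT_CLASSES <- c("noe_distance", "scalar_coupling", "rdc")
MEASUREMENT_SENSES <- c("equality", "upper_bound", "lower_bound")

# NMR restraint tables and PDB files disagree on primed-hydrogen and
# phosphate-oxygen naming; all dialects are normalized to the PDB v3 name.
ATOM_NAME_ALIASES <- c(
  "H5'1" = "H5'",  "1H5'" = "H5'",  "H5*"  = "H5'",
  "H5'2" = "H5''", "2H5'" = "H5''", "H5''" = "H5''", "H5\"" = "H5''",
  "H2'1" = "H2'",  "1H2'" = "H2'",  "H2*"  = "H2'",
  "O1P"  = "OP1",  "O2P"  = "OP2",
  "C1*"  = "C1'",  "C2*"  = "C2'", "C3*" = "C3'", "C4*" = "C4'",
  "C5*"  = "C5'",  "O3*"  = "O3'", "O4*" = "O4'", "O5*" = "O5'"
)

#' Canonicalize an atom name
#'
#' Maps primed-hydrogen and phosphate-oxygen naming dialects (H5'1, 1H5',
#' H2'1, O1P, star notation) onto standard PDB v3 names.  Unknown names pass
#' through unchanged.
#'
#' @param name character vector of atom names.
#' @export
canonical_atom_name <- function(name) {
  hit <- ATOM_NAME_ALIASES[name]
  out <- ifelse(is.na(hit), name, hit)
  unname(out)
}

BACKBONE_TORSIONS <- c("alpha", "beta", "gamma", "delta", "epsilon",
                       "zeta", "chi")

#' Build a measurement table
#'
#' Validates and assembles a set of experimental measurements into a
#' data.frame of class `rw_measurements`.
#'
#' @param df data.frame with the measurement columns (see Details in
#'   [parse_measurements()]); missing optional columns are filled.
#' @return data.frame of class `rw_measurements`.
#' @export
as_measurements <- function(df) {
  opt <- list(resid3 = NA_integer_, atom3 = NA_character_,
              resid4 = NA_integer_, atom4 = NA_character_,
              torsion_name = NA_character_, sense = "equality",
              dataset = "A", coupling_type = NA_character_)
  for (nm in names(opt)) if (!nm %in% names(df)) df[[nm]] <- opt[[nm]]
  # pin column types so all-NA optional columns compare equal on re-parse
  for (nm in c("resid1", "resid2", "resid3", "resid4"))
    df[[nm]] <- as.integer(df[[nm]])
  for (nm in c("id", "class", "atom1", "atom2", "atom3", "atom4",
               "torsion_name", "sense", "dataset", "coupling_type"))
    df[[nm]] <- as.character(df[[nm]])
  for (nm in c("value", "sigma")) df[[nm]] <- as.numeric(df[[nm]])
  req <- c("id", "class", "resid1", "atom1", "resid2", "atom2",
           "value", "sigma")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing measurement columns: ",
                         paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("duplicate measurement ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  bad <- which(!df$class %in% MEASUREMENT_CLASSES)
  if (length(bad))
    stop("unknown observable class '", df$class[bad[1]], "' in row ", bad[1])
  bad <- which(!df$sense %in% MEASUREMENT_SENSES)
  if (length(bad))
    stop("unknown sense '", df$sense[bad[1]], "' in row ", bad[1])
  bad <- which(!is.finite(df$sigma) | df$sigma <= 0)
  if (length(bad))
    stop("sigma must be > 0; offending row(s): ",
         paste(bad, collapse = ", "), " (id ",
         paste(df$id[bad], collapse = ", "), ")")
  bad <- which(df$class == "noe_distance" & df$value <= 0)
  if (length(bad))
    stop("noe_distance value must be > 0; offending row(s): ",
         paste(bad, collapse = ", "))
  cpl <- df$class == "scalar_coupling"
  if (any(cpl & is.na(df$torsion_name) &
          (is.na(df$resid3) | is.na(df$resid4))))
    stop("scalar_coupling rows need either torsion_name or four atoms")
  if (any(cpl & is.na(df$coupling_type)))
    stop("scalar_coupling rows need coupling_type")
  for (a in c("atom1", "atom2", "atom3", "atom4"))
    df[[a]] <- ifelse(is.na(df[[a]]), df[[a]], canonical_atom_name(df[[a]]))
  same <- df$resid1 == df$resid2 & df$atom1 == df$atom2
  if (any(same & df$class != "scalar_coupling"))
    stop("selectors must resolve to distinct atoms; row(s): ",
         paste(which(same & df$class != "scalar_coupling"), collapse = ", "))
  class(df) <- c("rw_measurements", "data.frame")
  df
}

#' Parse a measurement table from TSV or CSV
#'
#' One measurement per row.  Units are validated per observable class
#' (Angstrom for `noe_distance`, Hz for `scalar_coupling` and `rdc`);
#' duplicate ids and non-positive sigmas are rejected with the offending row
#' named.  Scalar couplings may name a backbone torsion (`torsion_name`
#' column: alpha..zeta, chi, evaluated on `resid1`) instead of listing four
#' atoms.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return data.frame of class `rw_measurements`.
#' @export
parse_measurements <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  # quote = "": primed atom names (H1', H5'') are data, not quoting
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          quote = "", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  as_measurements(df)
}

#' Write a measurement table as TSV
#' @param m an `rw_measurements` table.
#' @param path output path.
#' @export
write_measurements <- function(m, path) {
  utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Resolve measurement atom selectors against an ensemble topology
#'
#' A pure lookup: every (residue index, atom name) selector is mapped to a
#' row index of the ensemble's atom table, applying the atom-name alias
#' table.  All unresolved selectors are collected and reported together in a
#' single error.
#'
#' @param measurements an `rw_measurements` table.
#' @param ens an `rw_ensemble`.
#' @return integer matrix with one row per measurement and columns
#'   `i1..i4` (NA where a selector slot is unused).
#' @export
bind_selectors <- function(measurements, ens) {
  stopifnot(inherits(ens, "rw_ensemble"))
  key <- paste(ens$atoms$resno, canonical_atom_name(ens$atoms$atom))
  lookup <- function(resid, atom) {
    out <- rep(NA_integer_, length(resid))
    use <- !is.na(resid) & !is.na(atom)
    out[use] <- match(paste(resid[use], canonical_atom_name(atom[use])), key)
    out
  }
  idx <- cbind(i1 = lookup(measurements$resid1, measurements$atom1),
               i2 = lookup(measurements$resid2, measurements$atom2),
               i3 = lookup(measurements$resid3, measurements$atom3),
               i4 = lookup(measurements$resid4, measurements$atom4))
  # a torsion-named coupling needs no explicit atoms
  tor <- !is.na(measurements$torsion_name)
  need <- cbind(TRUE, TRUE, !is.na(measurements$resid3),
                !is.na(measurements$resid4))
  need[tor, ] <- FALSE
  bad <- which(need & is.na(idx), arr.ind = TRUE)
  if (nrow(bad)) {
    msgs <- apply(bad, 1, function(b) {
      r <- b[1]; k <- b[2]
      sprintf("%s: (%s, %s)", measurements$id[r],
              measurements[[paste0("resid", k)]][r],
              measurements[[paste0("atom", k)]][r])
    })
    stop("unresolved atom selectors:\n  ",
         paste(unique(msgs), collapse = "\n  "))
  }
  rownames(idx) <- measurements$id
  idx
}
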