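# Multi-conformer SDF input/output. Parsing and formatting of the V2000
# records is delegated to ChemmineR; this layer groups records into
# ensembles, attaches SD-tag metadata and normalizes energy units.

# Parse an SDF file into a list of plain records:
# list(elements, coords, bonds, datablock, header_name)
.parse_sdf_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  out <- vector("list", length(sdfs))
  for (k in seq_along(sdfs)) {
    s <- sdfs[[k]]
    ab <- ChemmineR::atomblock(s)
    bb <- ChemmineR::bondblock(s)
    if (is.null(dim(ab)) || nrow(ab) < 1L) {
      stop("malformed SDF record at ordinal ", k, " in ", path)
    }
    elements <- sub("_.*$", "", rownames(ab))
    coords <- unname(ab[, 1:3, drop = FALSE])
    if (length(bb) == 0L || is.null(dim(bb)) || nrow(bb) == 0L) {
      bonds <- data.frame(i = integer(), j = integer(),
                          order = integer(), aromatic = logical())
    } else {
      order_raw <- as.integer(bb[, 3])
      bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                          order = ifelse(order_raw == 4L, 1L, order_raw),
                          aromatic = order_raw == 4L)
    }
    out[[k]] <- list(elements = elements, coords = coords, bonds = bonds,
                     datablock = ChemmineR::datablock(s),
                     header_name = unname(ChemmineR::header(s)[1]))
  }
  out
}

.records_to_ensembles <- function(records, get_id, energy_tag, energy_unit) {
  if (!energy_unit %in% names(.ENERGY_FACTORS)) {
    stop("unknown energy unit '", energy_unit, "'; use one of: ",
         paste(names(.ENERGY_FACTORS), collapse = ", "))
  }
  factor_ <- .ENERGY_FACTORS[[energy_unit]]
  ids <- vapply(seq_along(records), function(k) get_id(records[[k]], k),
                character(1))
  # consecutive records with the same id form one ensemble
  grp <- cumsum(c(TRUE, ids[-1L] != ids[-length(ids)]))
  ensembles <- list()
  for (g in unique(grp)) {
    recs <- records[grp == g]
    id <- ids[grp == g][1L]
    first <- recs[[1L]]
    for (r in recs) {
      if (length(r$elements) != length(first$elements) ||
          !identical(sort(r$elements), sort(first$elements))) {
        stop("atom composition mismatch within compound ", id)
      }
    }
    mol <- molecule(id, first$elements, first$bonds)
    confs <- lapply(seq_along(recs), function(k) {
      db <- recs[[k]]$datablock
      e <- if (energy_tag %in% names(db)) db[[energy_tag]] else NULL
      e <- if (is.null(e) || is.na(e) || !nzchar(e)) NA_real_ else {
        as.numeric(e) * factor_
      }
      conformer(id, k - 1L, recs[[k]]$coords, energy = e)
    })
    ensembles[[id]] <- conformer_ensemble(mol, confs)
  }
  ensembles
}

#' Read a multi-conformer SDF file into conformer ensembles
#'
#' Consecutive records sharing the same compound-id SD tag are grouped into
#' one [conformer_ensemble()], preserving record order as conformer order.
#' Energies are read from `energy_tag` when present and converted to
#' kcal/mol according to `energy_unit`.
#'
#' @param path SDF file (V2000, one record per conformer).
#' @param id_tag SD tag holding the compound id (default "compound_id").
#' @param energy_tag SD tag holding the conformer energy (default
#'   "energy_kcal_mol"); records without it load with energy `NA`.
#' @param energy_unit unit of the stored energies: one of "kcal/mol",
#'   "kJ/mol", "eV", "hartree".
#' @return named list of [conformer_ensemble()] objects.
#' @export
read_conformer_sdf <- function(path, id_tag = "compound_id",
                               energy_tag = "energy_kcal_mol",
                               energy_unit = "kcal/mol") {
  records <- .parse_sdf_records(path)
  get_id <- function(rec, k) {
    id <- if (id_tag %in% names(rec$datablock)) rec$datablock[[id_tag]] else NULL
    if (is.null(id) || is.na(id) || !nzchar(id)) {
      stop("record ", k, " lacks the compound-id SD tag '", id_tag, "'")
    }
    as.character(id)
  }
  .records_to_ensembles(records, get_id, energy_tag, energy_unit)
}

#' Write conformer ensembles as a multi-record SDF file
#'
#' One V2000 record per conformer, compound id and energy stored as SD tags.
#' The energy tag is omitted for conformers without an energy.
#'
#' @inheritParams read_conformer_sdf
#' @param ensembles list of [conformer_ensemble()] objects.
#' @return invisibly, the total number of records written.
#' @export
write_conformer_sdf <- function(ensembles, path, id_tag = "compound_id",
                                energy_tag = "energy_kcal_mol") {
  stopifnot(length(ensembles) >= 1L)
  sdf_list <- list()
  cids <- character(0)
  for (ens in ensembles) {
    if (length(ens$conformers) == 0L) {
      stop("ensemble with empty conformer list: ", ens$molecule$compound_id)
    }
    mol <- ens$molecule
    n_atoms <- length(mol$elements)
    n_bonds <- nrow(mol$bonds)
    for (cf in ens$conformers) {
      ab <- cbind(cf$coords, matrix(0, n_atoms, 12))
      rownames(ab) <- paste(mol$elements, seq_len(n_atoms), sep = "_")
      colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
      if (n_bonds > 0L) {
        order_out <- ifelse(mol$bonds$aromatic, 4L, mol$bonds$order)
        bb <- cbind(mol$bonds$i, mol$bonds$j, order_out,
                    matrix(0L, n_bonds, 4))
      } else {
        bb <- matrix(0L, 0L, 7L)
      }
      colnames(bb) <- paste0("C", 1:7)
      rownames(bb) <- as.character(seq_len(nrow(bb)))
      db <- c(stats::setNames(mol$compound_id, id_tag))
      if (!is.na(cf$energy)) {
        db <- c(db, stats::setNames(sprintf("%.17g", cf$energy), energy_tag))
      }
      hdr <- c(Molecule_Name = mol$compound_id, Source = "", Comment = "",
               Counts_Line = sprintf(
                 "%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_atoms, n_bonds))
      sdf_list[[length(sdf_list) + 1L]] <-
        methods::new(methods::className("SDF", "ChemmineR"),
                     header = hdr, atomblock = ab, bondblock = bb,
                     datablock = db)
      cids <- c(cids, mol$compound_id)
    }
  }
  sdfset <- methods::new(methods::className("SDFset", "ChemmineR"),
                         SDF = sdf_list,
                         ID = make.unique(cids, sep = "_rec"))
  ChemmineR::write.SDF(sdfset, file = path, cid = FALSE)
  invisible(length(sdf_list))
}

#' Load a modelling dataset from an SDF file and a property table
#'
#' Inner-joins the conformer ensembles of `sdf_path` with the per-compound
#' property values of `table_path` (a CSV with `compound_id` and `value`
#' columns). Unmatched compounds on either side are dropped with a warning
#' stating how many.
#'
#' @inheritParams read_conformer_sdf
#' @param sdf_path multi-conformer SDF file.
#' @param table_path CSV file with header columns `compound_id`, `value`.
#' @param property_name name recorded on each [property_record()].
#' @param units unit string for the property.
#' @return a [conformer_dataset()].
#' @export
load_dataset <- function(sdf_path, table_path, property_name, units = "",
                         id_tag = "compound_id",
                         energy_tag = "energy_kcal_mol",
                         energy_unit = "kcal/mol") {
  ensembles <- read_conformer_sdf(sdf_path, id_tag, energy_tag, energy_unit)
  tab <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "value") %in% names(tab))) {
    stop("property table must have 'compound_id' and 'value' columns")
  }
  if (anyDuplicated(tab$compound_id)) {
    stop("duplicate compound_id rows in property table: ",
         paste(unique(tab$compound_id[duplicated(tab$compound_id)]),
               collapse = ", "))
  }
  vals <- suppressWarnings(as.numeric(tab$value))
  bad <- which(is.na(vals) & !is.na(tab$value))
  if (length(bad) > 0L) {
    stop("non-numeric property value in table row ", bad[1L],
         " (compound ", tab$compound_id[bad[1L]], ")")
  }
  shared <- intersect(names(ensembles), tab$compound_id)
  dropped_sdf <- setdiff(names(ensembles), shared)
  dropped_tab <- setdiff(tab$compound_id, shared)
  if (length(dropped_sdf) + length(dropped_tab) > 0L) {
    warning(length(dropped_sdf), " SDF compound(s) and ", length(dropped_tab),
            " table row(s) had no match and were dropped: ",
            paste(utils::head(c(dropped_sdf, dropped_tab), 10L), collapse = ", "))
  }
  if (length(shared) == 0L) stop("no compounds shared between SDF and table")
  props <- lapply(shared, function(id) {
    property_record(id, vals[match(id, tab$compound_id)], property_name, units)
  })
  names(props) <- shared
  conformer_dataset(ensembles[shared], props)
}

#' Summarize a deposited multi-conformer SDF file
#'
#' Accession-check tooling for externally deposited conformer sets whose SD
#' tag conventions are unknown: auto-detects plausible compound-id and
#' energy tags (unless given), groups records into ensembles, and reports
#' compound/conformer counts plus the dataset means of the per-compound
#' maximum and mean pairwise all-atom RMSD.
#'
#' @param sdf_path SDF file to inspect.
#' @param id_tag,energy_tag override tag auto-detection when non-`NULL`.
#' @param energy_unit unit for parsed energies.
#' @param max_compounds optionally cap the number of compounds analysed.
#' @return list with `tags_found`, `id_tag_used`, `energy_tag_used`,
#'   `n_compounds`, `n_conformers`, `mean_max_pairwise_rmsd`,
#'   `mean_mean_pairwise_rmsd`.
#' @export
deposited_data_check <- function(sdf_path, id_tag = NULL, energy_tag = NULL,
                                 energy_unit = "kcal/mol",
                                 max_compounds = Inf) {
  records <- .parse_sdf_records(sdf_path)
  tags <- unique(unlist(lapply(records, function(r) names(r$datablock))))
  if (is.null(id_tag)) {
    cand <- grep("(?i)(id|name|cmpd|compound|mol)", tags, value = TRUE,
                 perl = TRUE)
    cand <- setdiff(cand, grep("(?i)energ", cand, value = TRUE))
    id_tag <- if (length(cand) > 0L) cand[1L] else NA_character_
  }
  if (is.null(energy_tag)) {
    cand <- grep("(?i)energ|hartree|kcal|kj_mol|\\bev\\b", tags, value = TRUE,
                 perl = TRUE)
    energy_tag <- if (length(cand) > 0L) cand[1L] else "energy_kcal_mol"
  }
  get_id <- if (is.na(id_tag)) {
    function(rec, k) rec$header_name          # fall back to the title line
  } else {
    function(rec, k) {
      id <- if (id_tag %in% names(rec$datablock)) rec$datablock[[id_tag]] else NULL
      if (is.null(id) || !nzchar(id)) rec$header_name else as.character(id)
    }
  }
  ensembles <- .records_to_ensembles(records, get_id, energy_tag, energy_unit)
  if (is.finite(max_compounds) && length(ensembles) > max_compounds) {
    ensembles <- ensembles[seq_len(max_compounds)]
  }
  divs <- lapply(ensembles, pairwise_diversity, heavy_only = FALSE)
  maxes <- vapply(divs, function(d) {
    if (is.null(d$max_pairwise_rmsd)) NA_real_ else d$max_pairwise_rmsd
  }, numeric(1))
  means <- vapply(divs, function(d) {
    if (is.null(d$mean_pairwise_rmsd)) NA_real_ else d$mean_pairwise_rmsd
  }, numeric(1))
  list(tags_found = tags,
       id_tag_used = id_tag,
       energy_tag_used = energy_tag,
       n_compounds = length(ensembles),
       n_conformers = sum(vapply(ensembles, function(e) length(e$conformers),
                                 integer(1))),
       mean_max_pairwise_rmsd = mean(maxes, na.rm = TRUE),
       mean_mean_pairwise_rmsd = mean(means, na.rm = TRUE))
}
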