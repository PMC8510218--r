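# Data model and CSV readers/writers for binary-mixture datasets.

#' Construct a validated binary-mixture dataset
#'
#' A \code{mixture_dataset} couples a table of experimental data points (one
#' row per mixture composition/temperature measurement) with a table of
#' per-component molecular descriptors.  Component 1 is conventionally the
#' hydrogen-bond acceptor (HBA; descriptors computed on its cationic part),
#' component 2 the hydrogen-bond donor (HBD).
#'
#' Validation enforces: non-negative mole fractions that sum to 1 (pairs
#' within \code{renorm_tol} of 1 are renormalized, larger discrepancies are
#' data errors), positive temperature and property values, 0/1 halide
#' indicators with at most one of chloride/bromide set per component-1
#' chemical (and consistently so across its records), and that every
#' chemical id resolves in the component descriptor table.
#'
#' @param records data.frame with columns \code{record_id}, \code{comp1_id},
#'   \code{comp2_id}, \code{x1}, \code{x2}, \code{T_K}, \code{has_Cl},
#'   \code{has_Br}, \code{y}.
#' @param components data.frame or matrix of numeric descriptors, rows named
#'   by chemical id (or with a first column \code{chemical_id}).
#' @param renorm_tol tolerance on \code{|x1 + x2 - 1|} below which the pair
#'   is renormalized to sum exactly to 1.  Default \code{1e-6}.
#' @return An object of class \code{mixture_dataset}: a list with elements
#'   \code{records} and \code{components}.
#' @seealso \code{\link{read_mixture_table}}, \code{\link{unique_mixtures}},
#'   \code{\link{wm_features}}
#' @export
mixture_dataset <- function(records, components, renorm_tol = 1e-6) {
  required <- c("record_id", "comp1_id", "comp2_id", "x1", "x2",
                "T_K", "has_Cl", "has_Br", "y")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("mixture table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[required]
  components <- as_component_table(components)

  for (col in c("x1", "x2", "T_K", "has_Cl", "has_Br", "y")) {
    records[[col]] <- as.numeric(records[[col]])
    if (anyNA(records[[col]])) {
      stop("non-numeric or missing values in column '", col, "'",
           call. = FALSE)
    }
  }
  records$record_id <- as.character(records$record_id)
  records$comp1_id <- as.character(records$comp1_id)
  records$comp2_id <- as.character(records$comp2_id)
  if (anyDuplicated(records$record_id)) {
    stop("duplicated record_id values", call. = FALSE)
  }

  if (any(records$x1 < 0 | records$x2 < 0)) {
    stop("negative mole fractions in row(s): ",
         paste(which(records$x1 < 0 | records$x2 < 0), collapse = ", "),
         call. = FALSE)
  }
  s <- records$x1 + records$x2
  bad <- which(abs(s - 1) > renorm_tol)
  if (length(bad)) {
    stop("mole fractions x1 + x2 differ from 1 beyond tolerance in row(s): ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  }
  records$x1 <- records$x1 / s
  records$x2 <- records$x2 / s

  if (any(records$T_K <= 0)) {
    stop("non-positive temperature in row(s): ",
         paste(which(records$T_K <= 0), collapse = ", "), call. = FALSE)
  }
  if (any(records$y <= 0)) {
    stop("non-positive property values in row(s): ",
         paste(which(records$y <= 0), collapse = ", "), call. = FALSE)
  }
  for (col in c("has_Cl", "has_Br")) {
    if (!all(records[[col]] %in% c(0, 1))) {
      stop("column '", col, "' must be a 0/1 indicator", call. = FALSE)
    }
  }
  if (any(records$has_Cl + records$has_Br > 1)) {
    stop("records with both chloride and bromide indicators set: ",
         paste(which(records$has_Cl + records$has_Br > 1), collapse = ", "),
         call. = FALSE)
  }
  # halide indicators describe the component-1 chemical, so must be
  # constant within each comp1_id
  flag_sig <- paste(records$has_Cl, records$has_Br)
  n_sigs <- tapply(flag_sig, records$comp1_id, function(v) length(unique(v)))
  if (any(n_sigs > 1)) {
    stop("inconsistent halide indicators across records of component-1 ",
         "chemical(s): ", paste(names(n_sigs)[n_sigs > 1], collapse = ", "),
         call. = FALSE)
  }

  used <- unique(c(records$comp1_id, records$comp2_id))
  unresolved <- setdiff(used, rownames(components))
  if (length(unresolved)) {
    stop("chemical id(s) absent from the component descriptor table: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }

  rownames(records) <- NULL
  structure(list(records = records, components = components),
            class = "mixture_dataset")
}

# Coerce a descriptor table to a numeric matrix with chemical ids as
# rownames.  Accepts either rownamed input or a first column 'chemical_id'.
as_component_table <- function(components) {
  if (is.matrix(components)) {
    m <- components
  } else {
    components <- as.data.frame(components)
    if ("chemical_id" %in% names(components)) {
      ids <- as.character(components$chemical_id)
      components <- components[setdiff(names(components), "chemical_id")]
      rownames(components) <- ids
    }
    m <- as.matrix(components)
  }
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) {
    stop("component table must carry chemical ids (rownames or a ",
         "'chemical_id' column)", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicated chemical ids in component table", call. = FALSE)
  }
  if (anyNA(m)) {
    bad <- colnames(m)[colSums(is.na(m)) > 0]
    stop("missing descriptor values in column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m
}

#' @export
print.mixture_dataset <- function(x, ...) {
  r <- x$records
  cat("mixture_dataset:", nrow(r), "records,",
      length(unique(c(r$comp1_id, r$comp2_id))), "chemicals,",
      ncol(x$components), "descriptors\n")
  cat("  comp1 (HBA):", length(unique(r$comp1_id)),
      " comp2 (HBD):", length(unique(r$comp2_id)), "\n")
  cat("  T range [K]:", paste(range(r$T_K), collapse = " - "),
      "  y range:", paste(signif(range(r$y), 4), collapse = " - "), "\n")
  invisible(x)
}

#' Read the two CSV inputs of the mixture-QSPR workflow
#'
#' \code{read_component_table} reads a descriptor CSV whose first column is
#' \code{chemical_id} and whose remaining columns are named numeric
#' descriptors.  \code{read_mixture_table} reads a mixture data CSV and
#' validates it against the component table; \code{col_map} renames
#' non-standard headers (a named character vector mapping the internal names
#' \code{record_id}, \code{comp1_id}, \code{comp2_id}, \code{x1}, \code{x2},
#' \code{T_K}, \code{has_Cl}, \code{has_Br}, \code{y} to the file's headers).
#'
#' @param path path to a CSV file.
#' @param components a component table (from \code{read_component_table} or
#'   any form accepted by \code{\link{mixture_dataset}}).
#' @param col_map optional named character vector mapping internal column
#'   names to the file's column names.
#' @param renorm_tol passed to \code{\link{mixture_dataset}}.
#' @return \code{read_component_table}: a numeric matrix with chemical-id
#'   rownames.  \code{read_mixture_table}: a \code{mixture_dataset}.
#' @export
read_mixture_table <- function(path, components, col_map = NULL,
                               renorm_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  internal <- c("record_id", "comp1_id", "comp2_id", "x1", "x2",
                "T_K", "has_Cl", "has_Br", "y")
  map <- setNames(internal, internal)
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols)) {
    stop("mixture table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- raw[unname(map)]
  names(records) <- names(map)
  mixture_dataset(records, components, renorm_tol = renorm_tol)
}

#' @rdname read_mixture_table
#' @export
read_component_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(raw) >= 2) {
    stop("component table needs a chemical_id column plus at least one ",
         "descriptor column", call. = FALSE)
  }
  names(raw)[1] <- "chemical_id"
  as_component_table(raw)
}

#' Write the dataset back to its two CSV forms
#'
#' @param dataset a \code{mixture_dataset}.
#' @param mixtures_path,components_path output CSV paths (either may be
#'   \code{NULL} to skip).
#' @return Invisibly, the dataset.
#' @export
write_mixture_tables <- function(dataset, mixtures_path = NULL,
                                 components_path = NULL) {
  stopifnot(inherits(dataset, "mixture_dataset"))
  if (!is.null(mixtures_path)) {
    write.csv(dataset$records, mixtures_path, row.names = FALSE)
  }
  if (!is.null(components_path)) {
    out <- data.frame(chemical_id = rownames(dataset$components),
                      dataset$components, check.names = FALSE)
    write.csv(out, components_path, row.names = FALSE)
  }
  invisible(dataset)
}

# Per-record mixture key: comp1 | comp2 | x1:x2 rounded to ratio_digits.
# Two records with the same key are the same mixture regardless of
# temperature.
record_mixture_keys <- function(dataset, ratio_digits = 4) {
  r <- dataset$records
  sig <- sprintf(paste0("%.", ratio_digits, "f:%.", ratio_digits, "f"),
                 r$x1, r$x2)
  paste(r$comp1_id, r$comp2_id, sig, sep = "|")
}

#' Enumerate the unique mixtures of a dataset
#'
#' A mixture is identified by its two components and their molar ratio
#' (rounded to \code{ratio_digits} decimals), so the same chemical pair at
#' e.g. 1:1 and 2:1 counts as two mixtures.  Mixtures are returned sorted by
#' number of instances (records) in descending order, ties broken by first
#' occurrence in record order.
#'
#' @param dataset a \code{mixture_dataset}.
#' @param ratio_digits decimals used to compare molar ratios (default 4).
#' @return data.frame with columns \code{comp1_id}, \code{comp2_id},
#'   \code{ratio_signature}, \code{n_instances} and (internal) \code{key}.
#' @export
unique_mixtures <- function(dataset, ratio_digits = 4) {
  stopifnot(inherits(dataset, "mixture_dataset"))
  if (nrow(dataset$records) == 0) stop("empty dataset", call. = FALSE)
  keys <- record_mixture_keys(dataset, ratio_digits)
  first <- which(!duplicated(keys))
  tab <- data.frame(key = keys[first], stringsAsFactors = FALSE)
  counts <- table(factor(keys, levels = tab$key))
  tab$n_instances <- as.integer(counts)
  ord <- order(-tab$n_instances, seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  parts <- strsplit(tab$key, "|", fixed = TRUE)
  tab$comp1_id <- vapply(parts, `[[`, "", 1L)
  tab$comp2_id <- vapply(parts, `[[`, "", 2L)
  tab$ratio_signature <- vapply(parts, `[[`, "", 3L)
  rownames(tab) <- NULL
  tab[c("comp1_id", "comp2_id", "ratio_signature", "n_instances", "key")]
}
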