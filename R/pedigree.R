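# Pedigree data model: one row per individual, columns as in the standard
# dialect below. Sexes are "male"/"female"; "NA" is the missing marker.

PEDIGREE_COLUMNS <- c(
  "id", "sex", "father_id", "mother_id", "birth_year", "death_year",
  "emigration_year", "parish", "social_class", "twin", "first_born",
  "married", "marriage_year", "n_children"
)

REQUIRED_COLUMNS <- c("id", "sex", "father_id", "mother_id", "birth_year")

SOCIAL_CLASSES <- c("rich", "middle", "poor")

#' Coerce and validate a pedigree table
#'
#' A pedigree is a tibble with one row per individual and the columns
#' `id`, `sex`, `father_id`, `mother_id`, `birth_year`, `death_year`,
#' `emigration_year`, `parish`, `social_class`, `twin`, `first_born`,
#' `married`, `marriage_year`, `n_children`. Missing optional columns are
#' added as `NA`. Validation enforces unique ids, no self-parenting, acyclic
#' parent links, sex-consistent parent references, and chronologically
#' consistent vital years.
#'
#' @param x A data frame with at least `id`, `sex`, `father_id`, `mother_id`
#'   and `birth_year` columns.
#' @return A validated pedigree tibble (class `wmama_pedigree`).
#' @examples
#' ped <- as_pedigree(tibble::tibble(
#'   id = c("f", "m", "c"), sex = c("male", "female", "male"),
#'   father_id = c(NA, NA, "f"), mother_id = c(NA, NA, "m"),
#'   birth_year = c(1820, 1824, 1850)
#' ))
#' @export
as_pedigree <- function(x) {
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  x <- as_tibble(x)
  missing_req <- setdiff(REQUIRED_COLUMNS, names(x))
  if (length(missing_req) > 0) {
    abort(paste0(
      "Pedigree is missing required column(s): ",
      paste(missing_req, collapse = ", ")
    ))
  }
  for (col in setdiff(PEDIGREE_COLUMNS, names(x))) {
    x[[col]] <- switch(col,
      death_year = ,
      emigration_year = ,
      marriage_year = NA_real_,
      parish = ,
      social_class = NA_character_,
      twin = ,
      first_born = ,
      married = NA,
      n_children = NA_integer_
    )
  }
  x <- x[PEDIGREE_COLUMNS]
  x <- x |>
    mutate(
      id = as.character(.data$id),
      sex = tolower(as.character(.data$sex)),
      father_id = as.character(.data$father_id),
      mother_id = as.character(.data$mother_id),
      across(c("birth_year", "death_year", "emigration_year", "marriage_year"),
             as.numeric),
      across(c("twin", "first_born", "married"), as.logical),
      n_children = as.integer(.data$n_children)
    )
  validate_pedigree(x)
  class(x) <- c("wmama_pedigree", setdiff(class(x), "wmama_pedigree"))
  x
}

validate_pedigree <- function(x) {
  if (anyNA(x$id)) abort("Pedigree contains rows with missing `id`.")
  dup <- x$id[duplicated(x$id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate id(s) in pedigree: ",
                 paste(unique(dup), collapse = ", ")))
  }
  bad_sex <- !is.na(x$sex) & !x$sex %in% c("male", "female")
  if (any(bad_sex)) {
    abort(paste0("Invalid sex value(s): ",
                 paste(unique(x$sex[bad_sex]), collapse = ", ")))
  }
  self <- which(!is.na(x$father_id) & x$father_id == x$id |
                  !is.na(x$mother_id) & x$mother_id == x$id)
  if (length(self) > 0) {
    abort(paste0("Individual(s) listed as their own parent: ",
                 paste(x$id[self], collapse = ", ")))
  }
  idx <- setNames(seq_len(nrow(x)), x$id)
  f_idx <- idx[x$father_id]
  m_idx <- idx[x$mother_id]
  bad_f <- !is.na(f_idx) & x$sex[f_idx] != "male"
  if (any(bad_f, na.rm = TRUE)) {
    abort(paste0("father_id refers to a non-male record for: ",
                 paste(x$id[which(bad_f)], collapse = ", ")))
  }
  bad_m <- !is.na(m_idx) & x$sex[m_idx] != "female"
  if (any(bad_m, na.rm = TRUE)) {
    abort(paste0("mother_id refers to a non-female record for: ",
                 paste(x$id[which(bad_m)], collapse = ", ")))
  }
  bad_death <- !is.na(x$death_year) & !is.na(x$birth_year) &
    x$death_year < x$birth_year
  if (any(bad_death)) {
    abort(paste0("death_year precedes birth_year for: ",
                 paste(x$id[bad_death], collapse = ", ")))
  }
  bad_marr <- !is.na(x$marriage_year) & !is.na(x$birth_year) &
    x$marriage_year < x$birth_year
  if (any(bad_marr)) {
    abort(paste0("marriage_year precedes birth_year for: ",
                 paste(x$id[bad_marr], collapse = ", ")))
  }
  check_acyclic(x, idx)
  invisible(x)
}

# Cycle check over parent links: peel individuals whose parents are all
# resolved (Kahn's algorithm on the child -> parent dependency graph);
# anyone left unpeeled sits on a cycle, i.e. is their own ancestor.
check_acyclic <- function(x, idx) {
  n <- nrow(x)
  fa <- match(x$father_id, x$id)
  mo <- match(x$mother_id, x$id)
  npar <- (!is.na(fa)) + (!is.na(mo))
  parent <- c(fa, mo)
  child <- rep(seq_len(n), 2)
  ok <- !is.na(parent)
  children_of <- split(child[ok], parent[ok])
  processed <- logical(n)
  frontier <- which(npar == 0)
  while (length(frontier) > 0) {
    processed[frontier] <- TRUE
    kids <- unlist(children_of[as.character(frontier)], use.names = FALSE)
    if (length(kids) > 0) {
      npar <- npar - tabulate(kids, nbins = n)
      frontier <- which(npar == 0 & !processed)
    } else {
      frontier <- integer(0)
    }
  }
  if (any(!processed)) {
    abort(paste0("Pedigree contains a parent cycle involving id `",
                 x$id[which(!processed)[1]], "`."))
  }
  invisible(TRUE)
}

#' Read a pedigree from a delimited text file
#'
#' Reads a tab- or comma-delimited file with a header row into a validated
#' pedigree. The delimiter is sniffed from the header line. `"NA"` (and empty
#' fields) mark missing values. A `dialect` mapping allows files whose headers
#' differ from the standard column names.
#'
#' @param source Path to a delimited text file.
#' @param dialect Optional named character vector mapping standard column
#'   names to the file's header names, e.g. `c(id = "person", sex = "gender")`.
#' @return A pedigree tibble (see [as_pedigree()]).
#' @export
read_pedigree <- function(source, dialect = NULL) {
  header <- readLines(source, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(
    source, delim = delim, na = c("", "NA"),
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0(
      "Unparseable row(s) in `", source, "` at line(s): ",
      paste(unique(probs$row + 1), collapse = ", ")
    ))
  }
  if (!is.null(dialect)) {
    bad <- setdiff(dialect, names(raw))
    if (length(bad) > 0) {
      abort(paste0("dialect refers to absent file column(s): ",
                   paste(bad, collapse = ", ")))
    }
    names(raw)[match(dialect, names(raw))] <- names(dialect)
  }
  missing_req <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing_req) > 0) {
    abort(paste0("File `", source, "` is missing required column(s): ",
                 paste(missing_req, collapse = ", ")))
  }
  as_pedigree(raw)
}

#' Write a pedigree to a delimited text file
#'
#' The written file round-trips through [read_pedigree()] field-for-field,
#' including missing-value markers. An empty pedigree yields a header-only
#' file.
#'
#' @param pedigree A pedigree tibble.
#' @param sink Output file path.
#' @param delim Field delimiter; tab by default.
#' @return `sink`, invisibly.
#' @export
write_pedigree <- function(pedigree, sink, delim = "\t") {
  stopifnot(is.data.frame(pedigree))
  readr::write_delim(pedigree[PEDIGREE_COLUMNS], sink, delim = delim, na = "NA")
  invisible(sink)
}

#' Age of a father at a child's birth
#'
#' Computed as the difference of birth years (fractional years are honoured).
#' A non-positive difference is a pedigree inconsistency and raises an error;
#' ages outside the plausible human range 13--80 produce a warning but are
#' still returned.
#'
#' @param father,child Single individual records: one-row data frames or named
#'   lists carrying at least `birth_year` (and optionally `id` for messages).
#' @return Age in years (numeric scalar).
#' @examples
#' age_at_fathering(list(birth_year = 1820), list(birth_year = 1850)) # 30
#' @export
age_at_fathering <- function(father, child) {
  fb <- as.numeric(father[["birth_year"]])
  cb <- as.numeric(child[["birth_year"]])
  if (is.na(fb) || is.na(cb)) {
    abort("Both birth years must be present to compute an age at fathering.")
  }
  age <- cb - fb
  if (age <= 0) {
    abort(paste0(
      "Impossible ordering: father (born ", fb,
      ") is not older than child (born ", cb, ")."
    ))
  }
  if (age < 13 || age > 80) {
    warn(paste0("Age at fathering ", round(age, 2),
                " is outside the plausible range [13, 80]."))
  }
  age
}

# Male ancestors of the proband's lineage and the lineage member each one
# fathered, by generation: g1 the father (fathered the proband), g2 the two
# grandfathers (fathered the parents), g3 the four great-grandfathers
# (fathered the four grandparents).
LINEAGE_PATHS <- list(
  `1` = list(c("F")),
  `2` = list(c("F", "F"), c("M", "F")),
  `3` = list(c("F", "F", "F"), c("F", "M", "F"),
             c("M", "F", "F"), c("M", "M", "F"))
)

#' Collect a proband's male ancestors and their ages at fathering
#'
#' Walks the pedigree up to `max_generations` (father, grandfathers,
#' great-grandfathers), recording for each known male ancestor the age `a` at
#' which he fathered the next individual in the proband's lineage and the
#' coefficient of relationship `r = 0.5^g` for his generation `g`. Ancestors
#' that are unknown, or whose age cannot be computed because a birth year is
#' missing, are dropped and counted in a per-generation missing tally.
#'
#' @param pedigree A pedigree tibble.
#' @param proband_id Id of the focal individual.
#' @param max_generations Number of ancestral generations to traverse
#'   (1, 2 or 3).
#' @return An `ancestor_ages` object: a list with `proband_id`, `entries`
#'   (tibble of `ancestor_id`, `generation`, `lineage`, `age`, `weight`) and
#'   `missing_by_generation` (named integer vector).
#' @seealso [compute_wmama()]
#' @export
collect_male_ancestors <- function(pedigree, proband_id, max_generations = 3) {
  stopifnot(max_generations %in% 1:3)
  idx <- setNames(seq_len(nrow(pedigree)), pedigree$id)
  if (is.na(idx[proband_id])) {
    abort(paste0("Proband `", proband_id, "` not found in pedigree."))
  }
  # follow a lineage path of F/M steps from the proband; NA when it breaks
  follow <- function(path) {
    i <- idx[[proband_id]]
    for (step in path) {
      pid <- if (step == "F") pedigree$father_id[i] else pedigree$mother_id[i]
      if (is.na(pid) || is.na(idx[pid])) return(NA_integer_)
      i <- idx[[pid]]
    }
    i
  }
  entries <- list()
  missing <- setNames(integer(3), as.character(1:3))
  for (g in seq_len(max_generations)) {
    for (path in LINEAGE_PATHS[[as.character(g)]]) {
      anc_i <- follow(path)
      child_i <- if (length(path) == 1) idx[[proband_id]] else
        follow(path[-length(path)])
      ok <- !is.na(anc_i) && !is.na(child_i) &&
        !is.na(pedigree$birth_year[anc_i]) &&
        !is.na(pedigree$birth_year[child_i])
      if (!ok) {
        missing[g] <- missing[g] + 1L
        next
      }
      age <- age_at_fathering(pedigree[anc_i, ], pedigree[child_i, ])
      entries[[length(entries) + 1]] <- tibble(
        ancestor_id = pedigree$id[anc_i],
        generation = g,
        lineage = paste(path, collapse = ""),
        age = age,
        weight = 0.5^g
      )
    }
  }
  entries <- if (length(entries) > 0) bind_rows(entries) else
    tibble(ancestor_id = character(), generation = integer(),
           lineage = character(), age = numeric(), weight = numeric())
  structure(
    list(proband_id = proband_id, entries = entries,
         missing_by_generation = missing[seq_len(max_generations)]),
    class = "ancestor_ages"
  )
}

#' @export
print.ancestor_ages <- function(x, ...) {
  cat("<ancestor_ages> proband", x$proband_id, "-",
      nrow(x$entries), "known male ancestor(s),",
      sum(x$missing_by_generation), "missing\n")
  print(x$entries)
  invisible(x)
}
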