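#' @useDynLib speechdcm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rbinom runif sd var cor median quantile
#' @importFrom utils write.table read.delim read.csv write.csv
NULL

# PrG partner sets defining the seven families, in family-id order.
family_partners <- list(
  `1` = c("pSTG", "mSTG", "FuG"),
  `2` = c("mSTG", "FuG"),
  `3` = c("pSTG", "FuG"),
  `4` = c("pSTG", "mSTG"),
  `5` = "pSTG",
  `6` = "mSTG",
  `7` = "FuG"
)

allowed_codes <- function(family_id) {
  partners <- family_partners[[as.character(family_id)]]
  list(a = if ("pSTG" %in% partners) 1:4 else 1L,
       b = if ("mSTG" %in% partners) 2:3 else 1L,
       c = if ("FuG" %in% partners) 2:3 else 1L)
}

#' Build one candidate model from its family and factor codes
#'
#' Each candidate network is indexed by its family (which of the three
#' PrG bidirectional endogenous links exist) and three modulation codes.
#' Code `a` governs modulation between PrG and pSTG (1 none, 2 PrG->pSTG,
#' 3 pSTG->PrG, 4 bidirectional); codes `b` and `c` govern modulation
#' between PrG and mSTG / FuG respectively (1 none, 2 bottom-up to PrG,
#' 3 bidirectional). A code other than 1 is only permitted when the
#' corresponding endogenous link exists in the family.
#'
#' @param family_id integer 1..7.
#' @param a_code,b_code,c_code factor-2 modulation codes (see Details).
#' @param regions the canonical `region_set`.
#' @param pstg_bottom_up logical; keep the always-present bottom-up
#'   modulations mSTG->pSTG and FuG->pSTG in every model (default TRUE).
#' @return A `model_spec` object with binary matrices `A` (endogenous,
#'   diagonal structurally present), `B` (modulated connections) and driving
#'   vector `C` (inputs enter at mSTG and FuG in every model). Matrix
#'   convention: `A[i, j] = 1` means a directed connection from region j to
#'   region i.
#' @export
model_from_codes <- function(family_id, a_code, b_code, c_code,
                             regions = speech_regions(),
                             pstg_bottom_up = TRUE) {
  if (!is_canonical_regions(regions))
    stop("model space is defined over the canonical (PrG, pSTG, mSTG, FuG) region set",
         call. = FALSE)
  if (!family_id %in% 1:7)
    stop("family_id must be in 1..7", call. = FALSE)
  ok <- allowed_codes(family_id)
  partners <- family_partners[[as.character(family_id)]]
  if (!a_code %in% ok$a)
    stop(sprintf("a_code %d invalid for family %d: modulation between PrG and pSTG requires the PrG-pSTG endogenous link",
                 a_code, family_id), call. = FALSE)
  if (!b_code %in% ok$b)
    stop(sprintf("b_code %d invalid for family %d: modulation between PrG and mSTG requires the PrG-mSTG endogenous link",
                 b_code, family_id), call. = FALSE)
  if (!c_code %in% ok$c)
    stop(sprintf("c_code %d invalid for family %d: modulation between PrG and FuG requires the PrG-FuG endogenous link",
                 c_code, family_id), call. = FALSE)

  rn <- regions$names
  A <- matrix(0L, 4, 4, dimnames = list(rn, rn))
  diag(A) <- 1L
  core <- c("pSTG", "mSTG", "FuG")
  for (i in core) for (j in core) if (i != j) A[i, j] <- 1L
  for (p in partners) {
    A["PrG", p] <- 1L
    A[p, "PrG"] <- 1L
  }

  B <- matrix(0L, 4, 4, dimnames = list(rn, rn))
  if (a_code %in% c(2L, 4L)) B["pSTG", "PrG"] <- 1L
  if (a_code %in% c(3L, 4L)) B["PrG", "pSTG"] <- 1L
  if (b_code %in% c(2L, 3L)) B["PrG", "mSTG"] <- 1L
  if (b_code == 3L)          B["mSTG", "PrG"] <- 1L
  if (c_code %in% c(2L, 3L)) B["PrG", "FuG"] <- 1L
  if (c_code == 3L)          B["FuG", "PrG"] <- 1L
  if (pstg_bottom_up) {
    B["pSTG", "mSTG"] <- 1L
    B["pSTG", "FuG"] <- 1L
  }

  C <- c(PrG = 0L, pSTG = 0L, mSTG = 1L, FuG = 1L)

  structure(list(model_id = NA_integer_, family_id = as.integer(family_id),
                 a_code = as.integer(a_code), b_code = as.integer(b_code),
                 c_code = as.integer(c_code), A = A, B = B, C = C,
                 pstg_bottom_up = pstg_bottom_up),
            class = "model_spec")
}

#' Enumerate the factorial space of 44 candidate models
#'
#' Families are the seven non-empty subsets of PrG bidirectional endogenous
#' links; within each family the admissible modulation codes are enumerated
#' with `c` varying slowest, then `b`, then `a` fastest, and model ids are
#' assigned 1..44 in family order. This yields family sizes
#' (16, 4, 8, 8, 4, 2, 2).
#'
#' @inheritParams model_from_codes
#' @return A `model_space` object: list with `regions`, `models` (list of 44
#'   `model_spec`), and `families` (family_id -> model ids).
#' @examples
#' sp <- build_model_space()
#' length(sp$models)           # 44
#' lengths(sp$families)        # 16 4 8 8 4 2 2
#' @export
build_model_space <- function(regions = speech_regions(),
                              pstg_bottom_up = TRUE) {
  if (!is_canonical_regions(regions))
    stop("model space is defined over the canonical (PrG, pSTG, mSTG, FuG) region set",
         call. = FALSE)
  models <- list()
  id <- 0L
  for (fam in 1:7) {
    ok <- allowed_codes(fam)
    for (cc in ok$c) for (bb in ok$b) for (aa in ok$a) {
      id <- id + 1L
      m <- model_from_codes(fam, aa, bb, cc, regions, pstg_bottom_up)
      m$model_id <- id
      models[[id]] <- m
    }
  }
  fam_ids <- vapply(models, `[[`, integer(1), "family_id")
  families <- split(seq_along(models), fam_ids)
  names(families) <- as.character(sort(unique(fam_ids)))
  structure(list(regions = regions, models = models, families = families,
                 pstg_bottom_up = pstg_bottom_up),
            class = "model_space")
}

#' Check a model specification against the structural rules
#'
#' Reports (never raises) violations of the structural invariants: modulation
#' restricted to existing connections, driving inputs fixed at mSTG and FuG,
#' the fully bidirectional three-region core, zero B diagonal, and agreement
#' between the factor codes and the B matrix.
#'
#' @param spec a `model_spec`.
#' @return Character vector of violation descriptions; empty when valid.
#' @export
validate_model <- function(spec) {
  v <- character(0)
  rn <- canonical_region_names
  A <- spec$A; B <- spec$B; C <- spec$C
  if (!all(diag(A) == 1))
    v <- c(v, "diagonal of A must be structurally present in every model")
  if (any(diag(B) != 0))
    v <- c(v, "diagonal of B must be zero")
  off <- which(B == 1 & row(B) != col(B))
  if (any(A[off] != 1))
    v <- c(v, "every off-diagonal B entry requires the matching A entry (modulation only on existing connections)")
  if (!identical(as.integer(C), c(0L, 0L, 1L, 1L)))
    v <- c(v, "driving inputs are fixed at mSTG and FuG in every model")
  core <- c("pSTG", "mSTG", "FuG")
  for (i in core) for (j in core) if (i != j && A[i, j] != 1) {
    v <- c(v, "the mSTG/pSTG/FuG core must be fully bidirectionally connected")
    break
  }
  ref <- tryCatch(model_from_codes(spec$family_id, spec$a_code, spec$b_code,
                                   spec$c_code,
                                   pstg_bottom_up = isTRUE(spec$pstg_bottom_up)),
                  error = function(e) NULL)
  if (is.null(ref)) {
    v <- c(v, "family/code combination is not one of the 44 admissible models")
  } else {
    if (!identical(unname(ref$A), unname(A)))
      v <- c(v, "A matrix inconsistent with the family's PrG link set")
    if (!identical(unname(ref$B), unname(B)))
      v <- c(v, "B matrix inconsistent with the factor codes (a, b, c)")
  }
  v
}

#' Partition of the model space into families
#'
#' @param space a `model_space`.
#' @return Named list family_id -> integer vector of model ids; the blocks
#'   are pairwise disjoint and cover all model ids.
#' @export
family_partition <- function(space) {
  stopifnot(inherits(space, "model_space"))
  space$families
}

#' Write / read a model space as JSON
#'
#' Matrices are serialized row-major with rows = target region, columns =
#' source region, in the canonical order (PrG, pSTG, mSTG, FuG).
#'
#' @param space a `model_space`.
#' @param path file path.
#' @return `read_model_space` returns the reconstructed `model_space`.
#' @export
write_model_space <- function(space, path) {
  stopifnot(inherits(space, "model_space"))
  payload <- list(
    regions = list(names = space$regions$names,
                   mni = unname(apply(space$regions$mni, 1, as.integer,
                                      simplify = FALSE)),
                   radius_mm = space$regions$radius_mm),
    pstg_bottom_up = space$pstg_bottom_up,
    models = lapply(space$models, function(m) {
      list(model_id = m$model_id, family_id = m$family_id,
           codes = c(a = m$a_code, b = m$b_code, c = m$c_code),
           A = unname(apply(m$A, 1, as.integer, simplify = FALSE)),
           B = unname(apply(m$B, 1, as.integer, simplify = FALSE)),
           C = unname(as.integer(m$C)))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_space
#' @export
read_model_space <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  regions <- speech_regions(names = unlist(p$regions$names),
                            mni = do.call(rbind, lapply(p$regions$mni,
                                                        unlist)),
                            radius_mm = p$regions$radius_mm)
  space <- build_model_space(regions, pstg_bottom_up = isTRUE(p$pstg_bottom_up))
  # trust but verify: the JSON matrices must match the regenerated space
  for (k in seq_along(space$models)) {
    m <- space$models[[k]]
    row <- p$models[[k]]
    stored_A <- do.call(rbind, lapply(row$A, unlist))
    stored_B <- do.call(rbind, lapply(row$B, unlist))
    if (!identical(unname(m$A), matrix(as.integer(stored_A), 4, 4,
                                       byrow = FALSE)) ||
        !identical(unname(m$B), matrix(as.integer(stored_B), 4, 4,
                                       byrow = FALSE)))
      stop(sprintf("stored model %d disagrees with the factorial construction",
                   row$model_id), call. = FALSE)
  }
  space
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model %s (family %d; codes a%d, b%d, c%d)\n",
              ifelse(is.na(x$model_id), "?", x$model_id),
              x$family_id, x$a_code, x$b_code, x$c_code))
  edges <- function(M) {
    idx <- which(M == 1 & row(M) != col(M), arr.ind = TRUE)
    if (nrow(idx) == 0) return("none")
    paste(colnames(M)[idx[, 2]], "->", rownames(M)[idx[, 1]], collapse = ", ")
  }
  cat("  A:", edges(x$A), "\n")
  cat("  B:", edges(x$B), "\n")
  cat("  C:", paste(names(x$C)[x$C == 1], collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.model_space <- function(x, ...) {
  cat(sprintf("Model space: %d models in %d families (sizes %s)\n",
              length(x$models), length(x$families),
              paste(lengths(x$families), collapse = ", ")))
  invisible(x)
}
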