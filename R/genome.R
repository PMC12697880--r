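#' Architecture descriptor for the per-cell controller
#'
#' Every cell of the automaton runs an identical recurrent network: a sensor
#' embedding layer that maps each perceived neighbor state (its own state,
#' plus the 8 Moore neighbors under fixed boundary conditions) separately to a
#' `sensor_dim`-dimensional tanh embedding; the embeddings are mean-pooled
#' into a single context vector; a minimally gated recurrent layer of
#' dimension `hidden_dim` advances the cell's working memory; and a tanh
#' output head proposes an `n_state`-dimensional action, clipped to
#' `[-1, 1]`.
#'
#' The descriptor is recorded with every genome so genome files are
#' self-describing; all dimensions are free parameters of a run.
#'
#' @param width,height grid dimensions.
#' @param n_types number of cell types `N_G` (indicator channels).
#' @param n_hidden number of hidden state channels `N_H`.
#' @param sensor_dim dimension of the per-neighbor sensor embedding.
#' @param hidden_dim dimension of the recurrent (gated) controller layer.
#' @return an object of class `nca_architecture`.
#' @export
nca_architecture <- function(width = 16L, height = 16L, n_types = 3L,
                             n_hidden = 1L, sensor_dim = 8L, hidden_dim = 16L) {
  a <- list(width = as.integer(width), height = as.integer(height),
            n_types = as.integer(n_types), n_hidden = as.integer(n_hidden),
            n_state = as.integer(n_types + n_hidden),
            sensor_dim = as.integer(sensor_dim),
            hidden_dim = as.integer(hidden_dim),
            neighborhood = "moore")
  a$n_cells <- a$width * a$height
  class(a) <- "nca_architecture"
  a
}

#' @export
print.nca_architecture <- function(x, ...) {
  cat(sprintf(paste0("NCA architecture: %d x %d grid, N_G = %d, N_H = %d ",
                     "(N_C = %d), sensor dim %d, recurrent dim %d\n",
                     "  genome length: %d structural + %d functional = %d\n"),
              x$height, x$width, x$n_types, x$n_hidden, x$n_state,
              x$sensor_dim, x$hidden_dim,
              n_structural_genes(x), n_functional_genes(x), genome_length(x)))
  invisible(x)
}

#' Genome dimensions implied by an architecture
#'
#' The genome is the flat search-space vector of the evolutionary optimizer:
#' structural genes (the initial cell states, `n_cells * n_state` values,
#' clipped to the state bounds) followed by functional genes (the controller
#' parameters shared by all cells).
#'
#' @param arch an [nca_architecture()].
#' @return an integer count.
#' @export
n_structural_genes <- function(arch) arch$n_cells * arch$n_state

#' @rdname n_structural_genes
#' @export
n_functional_genes <- function(arch) {
  s <- arch$sensor_dim; h <- arch$hidden_dim; nc <- arch$n_state
  (s * nc + s) + 2L * (h * s + h * h + h) + (nc * h + nc)
}

#' @rdname n_structural_genes
#' @export
genome_length <- function(arch) n_structural_genes(arch) + n_functional_genes(arch)

take <- function(x, pos, n, dims = NULL) {
  v <- x[pos:(pos + n - 1L)]
  if (!is.null(dims)) v <- matrix(v, dims[1], dims[2])
  v
}

# unpack the functional gene vector into controller weight matrices
decode_controller <- function(theta, arch) {
  s <- arch$sensor_dim; h <- arch$hidden_dim; nc <- arch$n_state
  stopifnot(length(theta) == n_functional_genes(arch))
  p <- 1L
  g <- function(n, dims = NULL) {
    out <- take(theta, p, n, dims)
    p <<- p + n
    out
  }
  list(
    W_e = g(s * nc, c(s, nc)), b_e = g(s),
    W_f = g(h * s, c(h, s)), U_f = g(h * h, c(h, h)), b_f = g(h),
    W_c = g(h * s, c(h, s)), U_c = g(h * h, c(h, h)), b_c = g(h),
    W_o = g(nc * h, c(nc, h)), b_o = g(nc)
  )
}

#' Decode a flat parameter vector into a genome
#'
#' Splits the evolutionary search vector into structural genes (initial cell
#' states, clipped to the state bounds `[-3, 3]`) and functional genes (the
#' controller parameters), and unpacks the controller weights. Encoding a
#' decoded genome returns the clipped vector, so `decode(encode(g)) = g`.
#'
#' @param x numeric vector of length [genome_length()].
#' @param arch an [nca_architecture()].
#' @param l_c state bounds used to clip structural genes.
#' @return an object of class `nca_genome` with fields `structural`
#'   (`n_state x n_cells` matrix), `functional` (numeric vector), `params`
#'   (decoded controller weights) and `architecture`.
#' @export
decode_genome <- function(x, arch, l_c = c(-3, 3)) {
  if (length(x) != genome_length(arch)) {
    stop(sprintf("genome has length %d but architecture requires %d",
                 length(x), genome_length(arch)))
  }
  ns <- n_structural_genes(arch)
  structural <- matrix(pmin(pmax(x[seq_len(ns)], l_c[1]), l_c[2]),
                       nrow = arch$n_state, ncol = arch$n_cells)
  functional <- x[(ns + 1L):length(x)]
  g <- list(structural = structural, functional = functional,
            params = decode_controller(functional, arch),
            architecture = arch)
  class(g) <- "nca_genome"
  g
}

#' @rdname decode_genome
#' @param genome an `nca_genome`.
#' @export
encode_genome <- function(genome) {
  c(as.vector(genome$structural), genome$functional)
}

#' @export
print.nca_genome <- function(x, ...) {
  cat(sprintf("NCA genome: %d structural + %d functional genes\n",
              length(x$structural), length(x$functional)))
  print(x$architecture)
  invisible(x)
}

#' Read and write genomes as self-describing JSON
#'
#' The file stores the architecture descriptor, the structural genes, the
#' functional gene vector, and optionally the seed the genome was evolved
#' with, so a run can be replayed from the file alone.
#'
#' @param genome an `nca_genome`.
#' @param path file path.
#' @param seed optional creation seed recorded in the file.
#' @export
write_genome <- function(genome, path, seed = NULL) {
  a <- genome$architecture
  js <- list(architecture = unclass(a)[c("width", "height", "n_types",
                                         "n_hidden", "sensor_dim", "hidden_dim")],
             structural = as.vector(genome$structural),
             functional = genome$functional,
             seed = seed)
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  arch <- do.call(nca_architecture, as.list(js$architecture))
  g <- decode_genome(c(js$structural, js$functional), arch)
  if (!is.null(js$seed)) attr(g, "seed") <- js$seed
  g
}
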