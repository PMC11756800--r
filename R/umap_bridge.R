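# UMAP baseline.  The projection itself is delegated to the umap-learn
# implementation through the `python` interpreter on the PATH; data moves
# through temporary CSV files.  Used only as the comparison arm against the
# contrastive reducer - no package functionality depends on it elsewhere.

umap_python <- function() {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") stop("no python interpreter found for the UMAP baseline")
  py
}

#' Fit UMAP on training vectors and transform additional sets
#'
#' One fit, many transforms, all in a single interpreter call; the
#' embedding is seeded and therefore reproducible.
#'
#' @param train_x N x d matrix to fit on (N >= 10).
#' @param new_x optional list of matrices to transform with the fitted
#'   model.
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param seed random state.
#' @return list(train = N x 2 matrix, new = list of transformed matrices).
#' @export
umap_project <- function(train_x, new_x = list(), n_neighbors = 15L,
                         min_dist = 0.1, seed = 1L) {
  stopifnot(nrow(train_x) >= 10)
  td <- tempfile("umap")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  utils::write.csv(train_x, file.path(td, "train.csv"), row.names = FALSE)
  for (i in seq_along(new_x)) {
    utils::write.csv(new_x[[i]], file.path(td, sprintf("new_%03d.csv", i)),
                     row.names = FALSE)
  }
  script <- sprintf('
import warnings, numpy as np
warnings.filterwarnings("ignore")
import umap
d = %s
tr = np.loadtxt(d + "/train.csv", delimiter=",", skiprows=1)
m = umap.UMAP(n_components=2, n_neighbors=%d, min_dist=%f,
              random_state=%d, transform_seed=%d)
e = m.fit_transform(tr)
np.savetxt(d + "/out_train.csv", e, delimiter=",")
import glob, os
for f in sorted(glob.glob(d + "/new_*.csv")):
    x = np.loadtxt(f, delimiter=",", skiprows=1)
    if x.ndim == 1: x = x[None, :]
    y = m.transform(x)
    np.savetxt(d + "/out_" + os.path.basename(f), y, delimiter=",")
', deparse(td), as.integer(n_neighbors), min_dist, as.integer(seed),
    as.integer(seed))
  sf <- file.path(td, "run.py")
  writeLines(script, sf)
  # persist numba's JIT cache across calls within a session
  cache_dir <- file.path(tempdir(), "patternfit_numba_cache")
  dir.create(cache_dir, showWarnings = FALSE)
  status <- system2(umap_python(), sf, stdout = FALSE, stderr = FALSE,
                    env = paste0("NUMBA_CACHE_DIR=", cache_dir))
  if (status != 0 || !file.exists(file.path(td, "out_train.csv"))) {
    stop("UMAP baseline failed (python exit status ", status, ")")
  }
  tr <- as.matrix(utils::read.csv(file.path(td, "out_train.csv"),
                                  header = FALSE))
  dimnames(tr) <- NULL
  res_new <- lapply(seq_along(new_x), function(i) {
    m <- as.matrix(utils::read.csv(
      file.path(td, sprintf("out_new_%03d.csv", i)), header = FALSE))
    dimnames(m) <- NULL
    m
  })
  list(train = tr, new = res_new)
}
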