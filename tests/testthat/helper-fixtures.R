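# Shared fixtures, built lazily and cached for the whole test run. All
# fixtures are generated in code (no stored data).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# small Gabor bank for cheap unit tests (kernels up to 43 px)
small_bank <- function() fixture("small_bank", function()
  build_gabor_bank(n_scales = 2, n_orientations = 4))

# lat/lon grid mesh over a parametric surface patch
grid_mesh <- function(n, u_range, v_range, fxyz, color = NULL) {
  u <- seq(u_range[1], u_range[2], length.out = n)
  v <- seq(v_range[1], v_range[2], length.out = n)
  g <- expand.grid(u = u, v = v)
  verts <- fxyz(g$u, g$v)
  idx <- function(i, j) (j - 1L) * n + i
  i <- rep(1:(n - 1L), n - 1L)
  j <- rep(1:(n - 1L), each = n - 1L)
  tri <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
               cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  surface_mesh(verts, tri, if (is.null(color)) NULL else color(g$u, g$v))
}

sphere_patch_mesh <- function(n = 60, r = 100, half_angle = 1.2)
  grid_mesh(n, c(-half_angle, half_angle), c(-half_angle, half_angle),
            function(lon, lat)
              cbind(cos(lat) * sin(lon), sin(lat), cos(lat) * cos(lon)) * r)

# uniformly sampled full sphere point cloud
sphere_points <- function(n = 1000, r = 100, seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u / sqrt(rowSums(u^2)) * r
}

# small synthetic face population, prepared: stacks + 2D truth landmarks.
# grid_n reduced for speed; landmark geometry is unchanged by grid_n.
prepared_population <- function() fixture("prepared_population", function() {
  spec <- face_spec(seed = 42)
  pop <- generate_population(spec, 6)
  lapply(pop, prepare_subject)
})

# bunch graph + PC model trained on the first 5 prepared subjects with the
# small bank; subject 6 is the test subject
small_trained <- function() fixture("small_trained", function() {
  prep <- prepared_population()
  stacks <- lapply(prep[1:5], `[[`, "stack")
  lms <- lapply(prep[1:5], `[[`, "landmarks")
  graph <- train_bunch_graph(stacks, lms, small_bank())
  pc <- fit_pc_model(lms)
  test <- prep[[6]]
  maps <- gabor_responses(test$stack, small_bank(),
                          facemark:::needed_pixels(graph, 200))
  train_maps <- gabor_responses(stacks[[1]], small_bank(),
                                facemark:::needed_pixels(graph, 200))
  list(stacks = stacks, lms = lms, graph = graph, pc = pc, test = test,
       maps = maps, train_maps = train_maps)
})
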