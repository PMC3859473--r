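# Hand-built fixtures with known bookkeeping, constructed in code.

# Small consistent dataset: 3 zoos, 3 checklist orders (one never held).
# Primates: z = 4 held species, w = 2 threatened; totals p1=8, p2=60,
# p3=120, p4=2. Passeriformes: z = 2, w = 1; totals a1=55, a2=10.
# Testudines: in checklist, absent from zoos.
make_toy_dataset <- function() {
  zoos <- data.frame(zoo_id = c("z1", "z2", "z3"),
                     latitude = c(0, 10, 50),
                     longitude = c(0, 10, 100),
                     stringsAsFactors = FALSE)
  species <- data.frame(
    species_id = c("p1", "p2", "p3", "p4", "a1", "a2"),
    class_name = c(rep("Mammalia", 4), rep("Aves", 2)),
    order_name = c(rep("Primates", 4), rep("Passeriformes", 2)),
    category = c("VU", "LC", "EN", "LC", "LC", "VU"),
    stringsAsFactors = FALSE)
  holdings <- data.frame(
    zoo_id     = c("z1", "z2", "z1", "z2", "z3", "z3", "z1", "z2"),
    species_id = c("p1", "p1", "p2", "p3", "p3", "p4", "a1", "a2"),
    count      = c(5L, 3L, 60L, 100L, 20L, 2L, 55L, 10L),
    stringsAsFactors = FALSE)
  checklist <- data.frame(
    class_name = c("Mammalia", "Aves", "Reptilia"),
    order_name = c("Primates", "Passeriformes", "Testudines"),
    n_total = c(10L, 20L, 6L),
    n_threatened = c(4L, 5L, 3L),
    stringsAsFactors = FALSE)
  validate_dataset(zoos, species, holdings, checklist)
}

# Four-zoo cluster toy: three zoos within ~80 km each holding 20 of species
# "tx", a fourth ~5,000 km away holding none of it. At m = 50, r = 150 km
# the exhaustive attainment probability is exactly 3/4.
make_cluster_toy <- function() {
  zoos <- data.frame(zoo_id = c("A", "B", "C", "D"),
                     latitude = c(0, 0, 0.5, 0),
                     longitude = c(0, 0.5, 0, 45),
                     stringsAsFactors = FALSE)
  species <- data.frame(species_id = c("tx", "far"),
                        class_name = "Reptilia",
                        order_name = "Testudines",
                        category = c("EN", "VU"),
                        stringsAsFactors = FALSE)
  holdings <- data.frame(
    zoo_id = c("A", "B", "C", "D"),
    species_id = c("tx", "tx", "tx", "far"),
    count = c(20L, 20L, 20L, 60L),
    stringsAsFactors = FALSE)
  checklist <- data.frame(class_name = "Reptilia", order_name = "Testudines",
                          n_total = 10L, n_threatened = 6L,
                          stringsAsFactors = FALSE)
  validate_dataset(zoos, species, holdings, checklist)
}

# Small fast scenario for property tests: few zoos, small orders, fixed
# numbers of held species per order so the null is exactly hypergeometric.
make_null_scenario <- function(seed = 1L) {
  synthetic_scenario(
    n_zoos = 6,
    regions = data.frame(lat = c(45, -10), lon = c(5, 130),
                         share = c(0.5, 0.5), spread_km = c(300, 300)),
    orders = data.frame(
      class_name = c("Mammalia", "Aves", "Reptilia"),
      order_name = c("Carnivora", "Anseriformes", "Squamata"),
      n_total = c(200L, 100L, 500L),
      n_threatened = c(60L, 20L, 150L),
      z_target = c(40L, 30L, 60L),
      stringsAsFactors = FALSE),
    seed = seed)
}

# total variation distance between two PMFs on the same support
tv_distance <- function(p, q) sum(abs(p - q)) / 2

write_toy_csvs <- function(dataset, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_dataset(dataset, dir)
  dir
}
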