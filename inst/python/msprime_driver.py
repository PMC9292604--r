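"""Coalescent simulation backend.

Reads a JSON file describing one or more simulation scenarios
(isolation-with-migration demographies over a set of scaffolds) and writes
one TSV per scenario with columns: scaffold, pos (1-based), ref, alt and the
0/1 haplotype string across all sampled haplotypes. Only biallelic sites
segregating in the sample and polarizable against the ancestral state are
emitted. All randomness is seeded from the scenario seed.

Usage: python msprime_driver.py config.json
"""

import json
import sys

import numpy as np
import msprime
import tskit


def build_demography(sc, ne_scale, include_migration):
    dem = msprime.Demography()
    for p in sc["populations"]:
        dem.add_population(name=p["name"], initial_size=p["ne"] * ne_scale)
    for s in sc.get("splits", []):
        dem.add_population(name=s["ancestral"], initial_size=s["ne"] * ne_scale)
    for s in sorted(sc.get("splits", []), key=lambda x: x["time"]):
        dem.add_population_split(
            time=s["time"], derived=[s["childA"], s["childB"]],
            ancestral=s["ancestral"])
    for s in sc.get("size_changes", []):
        dem.add_population_parameters_change(
            time=s["time"], population=s["pop"],
            initial_size=s["ne"] * ne_scale)
    if include_migration:
        for m in sc.get("migrations", []):
            rate, p1, p2 = m["rate"], m["pop1"], m["pop2"]
            direction = m.get("direction", "both")
            if direction == "both":
                dem.add_symmetric_migration_rate_change(
                    time=m["start"], populations=[p1, p2], rate=rate)
                dem.add_symmetric_migration_rate_change(
                    time=m["end"], populations=[p1, p2], rate=0)
            else:
                # forward-time donor -> recipient maps to backwards-time
                # lineage movement recipient -> donor
                donor, recip = (p1, p2) if direction == "1>2" else (p2, p1)
                dem.add_migration_rate_change(
                    time=m["start"], rate=rate, source=recip, dest=donor)
                dem.add_migration_rate_change(
                    time=m["end"], rate=0, source=recip, dest=donor)
        for p in sc.get("pulses", []):
            # forward-time pulse: fraction of 'to' replaced by 'from'
            dem.add_mass_migration(
                time=p["time"], source=p["to"], dest=p["from"],
                proportion=p["fraction"])
    dem.sort_events()
    return dem


def write_variants(mts, name, fh):
    """Emit biallelic, ancestrally polarizable sites as TSV rows.

    tskit orders alleles with the ancestral state first, so a site whose
    genotype row contains exactly {0, 1} is observed-biallelic with REF =
    ancestral and ALT = allele 1. Everything is vectorized; only the final
    line assembly iterates.
    """
    if mts.num_sites == 0:
        return 0
    G = mts.genotype_matrix()
    keep = (G.max(axis=1) == 1) & (G.min(axis=1) == 0)
    if not keep.any():
        return 0
    sub = G[keep].astype(np.uint8)
    k = sub.shape[1]
    gts = (sub + 48).astype(np.uint8)
    gts = np.ascontiguousarray(gts).view(f"|S{k}").ravel()
    tab = mts.tables
    positions = tab.sites.position.astype(np.int64)[keep] + 1
    # decode ancestral states and first differing derived state per site
    anc_all = tskit.unpack_strings(tab.sites.ancestral_state,
                                   tab.sites.ancestral_state_offset)
    der_all = tskit.unpack_strings(tab.mutations.derived_state,
                                   tab.mutations.derived_state_offset)
    mut_site = tab.mutations.site
    first_der = {}
    for ms, ds in zip(mut_site, der_all):
        ms = int(ms)
        if ms not in first_der and ds != anc_all[ms]:
            first_der[ms] = ds
    idx = np.flatnonzero(keep)
    lines = []
    for j, site_id in enumerate(idx):
        site_id = int(site_id)
        alt = first_der.get(site_id)
        if alt is None:
            continue
        lines.append(f"{name}\t{positions[j]}\t{anc_all[site_id]}\t{alt}\t"
                     f"{gts[j].decode()}\n")
    fh.write("".join(lines))
    return len(lines)


def run_scenario(sc):
    seed = int(sc["seed"])
    rng = np.random.RandomState(seed)
    ne_scale = float(sc.get("ne_scale", 1.0))
    include_migration = not sc.get("disable_migration", False)
    dem = build_demography(sc, ne_scale, include_migration)
    samples = [msprime.SampleSet(int(s["n"]), population=s["population"],
                                 ploidy=int(s.get("ploidy", 2)))
               for s in sc["samples"]]
    mu = float(sc["mu"])
    rec = float(sc.get("r", 0.0))
    kappa = float(sc.get("kappa", 4.3))
    model = msprime.HKY(kappa=kappa)

    out = sc["out"]
    with open(out, "w") as fh:
        if sc.get("num_loci"):
            n_loci = int(sc["num_loci"])
            length = float(sc["locus_length"])
            seeds = rng.randint(1, 2**31 - 1, size=2 * n_loci)
            reps = msprime.sim_ancestry(
                samples=samples, demography=dem, sequence_length=length,
                recombination_rate=rec, random_seed=seeds[0],
                num_replicates=n_loci)
            for i, ts in enumerate(reps):
                if mu > 0:
                    mts = msprime.sim_mutations(
                        ts, rate=mu, random_seed=int(seeds[n_loci + i]),
                        model=model)
                else:
                    mts = ts
                write_variants(mts, f"locus_{i + 1}", fh)
        else:
            scaffolds = sc["scaffolds"]
            seeds = rng.randint(1, 2**31 - 1, size=2 * len(scaffolds))
            for i, sca in enumerate(scaffolds):
                ts = msprime.sim_ancestry(
                    samples=samples, demography=dem,
                    sequence_length=float(sca["length"]),
                    recombination_rate=rec, random_seed=int(seeds[2 * i]))
                if mu > 0:
                    mts = msprime.sim_mutations(
                        ts, rate=mu, random_seed=int(seeds[2 * i + 1]),
                        model=model)
                else:
                    mts = ts
                write_variants(mts, sca["name"], fh)
    return out


def main():
    with open(sys.argv[1]) as fh:
        config = json.load(fh)
    for sc in config["scenarios"]:
        run_scenario(sc)
        sys.stdout.write(f"done\t{sc.get('id', '')}\n")


if __name__ == "__main__":
    main()
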