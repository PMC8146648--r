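"""Coalescent simulation backend for the svadapt R package.

Reads a JSON model description, runs msprime, and writes a plain-text
haplotype block per replicate (binary 0/1 alleles, ancestral = 0) plus,
when an archaic pulse is configured, the true introgressed tract per
sampled haplotype (recovered from census nodes on the archaic branch).
"""
import json
import sys

import msprime
import numpy as np


def build_demography(spec):
    dem = msprime.Demography()
    for pop in spec["populations"]:
        dem.add_population(name=pop["name"], initial_size=pop["size"])
    mig = spec.get("migration", 0.0)
    arc_name = (spec.get("archaic") or {}).get("name")
    if mig > 0:
        # symmetric migration among extant *modern* populations only; the
        # archaic branch exchanges migrants with nobody
        extant = [p["name"] for p in spec["populations"]
                  if p.get("extant", True) and p["name"] != arc_name]
        for i, a in enumerate(extant):
            for b in extant[i + 1:]:
                dem.set_migration_rate(a, b, mig)
                dem.set_migration_rate(b, a, mig)
    events = []
    for sp in spec.get("splits", []):
        events.append(("split", sp["time"], sp))
    arc = spec.get("archaic")
    census_time = None
    if arc is not None and arc.get("pulse_frac", 0.0) > 0:
        census_time = arc["pulse_time"] + 0.5
        # resolve the recipient to whichever lineage is ancestral to it at
        # the pulse time (the named population may already have merged)
        recipient = arc["recipient"]
        for sp in sorted(spec.get("splits", []), key=lambda s: s["time"]):
            if sp["time"] <= arc["pulse_time"] and recipient in sp["derived"]:
                recipient = sp["ancestral"]
        arc = dict(arc, recipient=recipient)
        events.append(("pulse", arc["pulse_time"], arc))
        events.append(("census", census_time, None))
    events.sort(key=lambda e: e[1])
    for kind, time, payload in events:
        if kind == "split":
            dem.add_population_split(
                time=time, derived=payload["derived"], ancestral=payload["ancestral"])
        elif kind == "pulse":
            dem.add_mass_migration(
                time=time, source=payload["recipient"], dest=payload["name"],
                proportion=payload["pulse_frac"])
        elif kind == "census":
            dem.add_census(time=time)
    dem.sort_events()
    return dem, census_time


def introgressed_tracts(ts, arc_pop_id, census_time):
    """Per-sample-node introgressed intervals via archaic census nodes."""
    census = [n.id for n in ts.nodes()
              if n.population == arc_pop_id and n.time == census_time]
    census = set(census)
    tracts = {s: [] for s in ts.samples()}
    for tree in ts.trees():
        left, right = tree.interval
        for u in census:
            for s in tree.samples(u):
                tracts[s].append((left, right))
    merged = {}
    for s, iv in tracts.items():
        iv.sort()
        out = []
        for l, r in iv:
            if out and l <= out[-1][1]:
                out[-1] = (out[-1][0], max(out[-1][1], r))
            else:
                out.append((l, r))
        merged[s] = out
    return merged


def main():
    spec = json.load(open(sys.argv[1]))
    out = open(sys.argv[2], "w")
    dem, census_time = build_demography(spec)
    n_rep = spec.get("replicates", 1)
    rng = np.random.RandomState(spec["seed"])
    seeds = rng.randint(1, 2**31 - 1, size=(n_rep, 2))
    samples = {k: v for k, v in spec["samples"].items() if v > 0}
    pop_of_hap = []
    arc_name = spec.get("archaic", {}).get("name") if spec.get("archaic") else None
    for rep in range(n_rep):
        ts = msprime.sim_ancestry(
            samples=samples, demography=dem, ploidy=2,
            sequence_length=spec["length"],
            recombination_rate=spec.get("recombination_rate", 0.0),
            random_seed=int(seeds[rep, 0]))
        ts = msprime.sim_mutations(
            ts, rate=spec.get("mutation_rate", 0.0),
            model=msprime.BinaryMutationModel(),
            random_seed=int(seeds[rep, 1]), discrete_genome=True)
        keep = []
        for var in ts.variants():
            g = var.genotypes
            if g.min() != g.max():
                keep.append((int(var.site.position) + 1, g.copy()))
        out.write(">REP %d\n" % (rep + 1))
        pops = [ts.population(ts.node(s).population).metadata["name"]
                for s in ts.samples()]
        out.write("POPS %s\n" % " ".join(pops))
        out.write("POS %s\n" % " ".join(str(p) for p, _ in keep))
        if census_time is not None:
            arc_id = [p.id for p in ts.populations()
                      if p.metadata["name"] == arc_name][0]
            tr = introgressed_tracts(ts, arc_id, census_time)
            for idx, s in enumerate(ts.samples()):
                for l, r in tr[s]:
                    out.write("TRACT %d %d %d\n" % (idx + 1, int(l) + 1, int(r)))
        if keep:
            mat = np.stack([g for _, g in keep], axis=1)
        else:
            mat = np.zeros((len(pops), 0), dtype=int)
        for row in mat:
            out.write("HAP %s\n" % "".join(str(int(x)) for x in row))
        out.write("END\n")
    out.close()


if __name__ == "__main__":
    main()
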