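-- Relational schema of the NP-likeness store. The package persists
-- these tables as TSV files (one per table) inside the store directory;
-- this DDL documents the equivalent SQL layout for users who want to
-- load a dump into a relational engine.

CREATE TABLE ori_molecule (
    ori_id          INTEGER PRIMARY KEY,
    source_id       TEXT,            -- identifier in the source database
    smiles          TEXT NOT NULL,
    inchikey        TEXT,
    submission_date TEXT,
    source_db       TEXT,
    status          TEXT NOT NULL    -- NP | SM | BIOGENIC
);  -- rows may be redundant: one per submitted record

CREATE TABLE molecule (
    molecule_id               INTEGER PRIMARY KEY,
    smiles                    TEXT NOT NULL,      -- canonical, stereo-free
    inchi                     TEXT NOT NULL UNIQUE, -- structural identity
    is_np                     BOOLEAN NOT NULL,
    train_class               TEXT NOT NULL,      -- NP | SM | NONE
    contains_sugar            BOOLEAN NOT NULL,
    score_with_sugar          DOUBLE,
    score_without_sugar       DOUBLE,
    heavy_atom_count          INTEGER NOT NULL,
    total_atom_count          INTEGER NOT NULL,
    heavy_atom_count_no_sugar INTEGER,
    total_atom_count_no_sugar INTEGER,
    ring_count                INTEGER NOT NULL,
    n_repeated_fragments      INTEGER NOT NULL,   -- distinct non-H-centred
                                                  -- signatures with count >= 2
    c_count                   INTEGER NOT NULL,
    o_count                   INTEGER NOT NULL,
    n_count                   INTEGER NOT NULL
);

CREATE TABLE fragment_with_sugar (
    fragment_id      INTEGER PRIMARY KEY,
    canonical_string TEXT NOT NULL UNIQUE,  -- canonical atom signature
    height           INTEGER NOT NULL,
    np_count         INTEGER NOT NULL,
    sm_count         INTEGER NOT NULL,
    score            DOUBLE                  -- NULL until trained
);

CREATE TABLE fragment_without_sugar (
    fragment_id      INTEGER PRIMARY KEY,
    canonical_string TEXT NOT NULL UNIQUE,
    height           INTEGER NOT NULL,
    np_count         INTEGER NOT NULL,
    sm_count         INTEGER NOT NULL,
    score            DOUBLE
);

CREATE TABLE molecule_fragment_cpd (
    molecule_id INTEGER NOT NULL REFERENCES molecule(molecule_id),
    fragment_id INTEGER NOT NULL,  -- into the table selected by sugar_mode
    sugar_mode  TEXT NOT NULL,     -- WITH_SUGAR | WITHOUT_SUGAR
    occurrence  INTEGER NOT NULL CHECK (occurrence >= 1)
);
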