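# 23-node toy network used in the worked example.
# The published description fixes only local structure: Nei(v4) =
# {v1,v2,v3,v5,v11,v12}; Nei(v3) = {v1,v2,v4,v9,v10}; Nei(v5) = {v2,v4,v14};
# Ks(v4) = 3, d(v4) = 6; Ks(v3) = 3, d(v3) = 5; kmax = 6; 23 nodes total.
# The rest of the topology below is one frozen SYNTHETIC completion
# consistent with those constraints and with the published relative
# influence order of the core nodes (v4 > v2 > v3 > v1): a K4 core v1-v4
# plus pendant triangles and peripheral chains. Tests assert only the
# published constraints, never the free choices made here.
v1	v2
v1	v3
v1	v4
v2	v3
v2	v4
v3	v4
v4	v5
v4	v11
v4	v12
v3	v9
v3	v10
v2	v5
v5	v14
v2	v8
v2	v13
v1	v6
v6	v7
v9	v10
v11	v12
v14	v15
v8	v16
v16	v17
v17	v18
v18	v19
v19	v20
v20	v21
v21	v22
v22	v23
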