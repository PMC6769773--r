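group	mirna
group1	hsa-miR-1185-2-3p
group1	hsa-miR-553
group1	hsa-miR-144-3p
group1	hsa-miR-146b-5p
group1	hsa-miR-148b-3p
group1	hsa-miR-1976
group1	hsa-miR-19b-3p
group1	hsa-miR-526a
group1	hsa-miR-219a-2-3p
group1	hsa-miR-25-3p
group1	hsa-miR-26b-5p
group1	hsa-miR-301a-3p
group1	hsa-miR-513a-3p
group1	hsa-miR-552-3p
group1	hsa-miR-584-5p
group1	hsa-miR-613
group1	hsa-miR-615-5p
group2	hsa-miR-1185-1-3p
group2	hsa-miR-1197
group2	hsa-miR-1266-5p
group2	hsa-miR-149-5p
group2	hsa-miR-23a-3p
group2	hsa-miR-3161
group2	hsa-miR-331-3p
group2	hsa-miR-331-5p
group2	hsa-miR-337-5p
group2	hsa-miR-3615
group2	hsa-miR-409-3p
group2	hsa-miR-4455
group2	hsa-miR-498
group2	hsa-miR-520g-3p
group2	hsa-miR-584-5p
group2	hsa-miR-590-5p
group2	hsa-miR-625-5p
group2	hsa-miR-628-5p
group2	hsa-miR-651-5p
group3	hsa-miR-125a-3p
group3	hsa-miR-1281
group3	hsa-miR-128-2-5p
group3	hsa-miR-1305
group3	hsa-miR-223-3p
group3	hsa-miR-325
group3	hsa-miR-497-5p
group3	hsa-miR-500a-5p
group3	hsa-miR-548h-3p
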