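"operator_id","case_id","node_order","date_order","outcome","attending_assist","cytopathologist","midazolam_mg","fentanyl_ug"
"A","A-001",1,1,"S",0,0,9,175
"A","A-001",2,2,"F",0,0,9,175
"C","C-001",1,3,"S",1,1,6.5,150
"B","B-001",1,4,"S",0,0,5.5,75
"A","A-002",1,5,"F",0,1,8,125
"A","A-002",2,6,"F",0,1,8,125
"A","A-002",3,7,"S",0,1,8,125
"B","B-002",1,8,"S",0,1,7.5,125
"B","B-002",2,9,"S",0,1,7.5,125
"B","B-002",3,10,"S",0,1,7.5,125
"A","A-003",1,11,"S",0,0,13,125
"A","A-003",2,12,"S",0,0,13,125
"B","B-003",1,13,"F",1,0,9.5,75
"B","B-003",2,14,"S",1,0,9.5,75
"C","C-002",1,15,"S",0,1,8,75
"C","C-002",2,16,"S",0,1,8,75
"B","B-004",1,17,"S",0,0,3,175
"B","B-004",2,18,"F",0,0,3,175
"A","A-004",1,19,"S",0,0,7,75
"C","C-003",1,20,"S",0,0,10.5,75
"A","A-005",1,21,"S",0,0,7,175
"A","A-005",2,22,"S",0,0,7,175
"C","C-004",1,23,"F",0,0,16.5,200
"B","B-005",1,24,"S",0,0,11,150
"B","B-006",1,25,"S",0,0,7,275
"B","B-006",2,26,"F",0,0,7,275
"A","A-006",1,27,"S",0,0,7,75
"A","A-006",2,28,"S",0,0,7,75
"C","C-005",1,29,"F",0,0,9.5,100
"B","B-007",1,30,"S",0,0,8.5,75
"A","A-007",1,31,"F",0,0,4.5,100
"B","B-008",1,32,"F",0,0,5,100
"B","B-008",2,33,"S",0,0,5,100
"A","A-008",1,34,"S",1,1,11,200
"A","A-008",2,35,"S",1,1,11,200
"A","A-008",3,36,"S",1,1,11,200
"C","C-006",1,37,"F",0,0,6.5,250
"C","C-006",2,38,"S",0,0,6.5,250
"B","B-009",1,39,"F",0,1,6.5,75
"B","B-009",2,40,"S",0,1,6.5,75
"A","A-009",1,41,"S",1,0,9.5,100
"A","A-009",2,42,"F",1,0,9.5,100
"B","B-010",1,43,"S",0,0,10.5,150
"B","B-010",2,44,"F",0,0,10.5,150
"C","C-007",1,45,"S",1,1,10.5,75
"B","B-011",1,46,"S",1,0,8.5,100
"B","B-011",2,47,"S",1,0,8.5,100
"A","A-010",1,48,"S",1,1,8,150
"C","C-008",1,49,"S",1,1,9.5,125
"C","C-008",2,50,"S",1,1,9.5,125
"A","A-011",1,51,"S",1,1,5.5,100
"B","B-012",1,52,"S",0,0,9,100
"B","B-013",1,53,"F",0,1,6.5,175
"B","B-013",2,54,"S",0,1,6.5,175
"C","C-009",1,55,"S",1,1,12.5,100
"C","C-009",2,56,"S",1,1,12.5,100
"A","A-012",1,57,"S",1,1,6.5,200
"A","A-013",1,58,"S",1,1,9.5,150
"A","A-013",2,59,"S",1,1,9.5,150
"B","B-014",1,60,"S",0,0,10,125
"A","A-014",1,61,"S",1,0,10.5,250
"A","A-014",2,62,"S",1,0,10.5,250
"A","A-014",3,63,"S",1,0,10.5,250
"B","B-015",1,64,"S",0,0,9,75
"B","B-015",2,65,"S",0,0,9,75
"B","B-015",3,66,"S",0,0,9,75
"C","C-010",1,67,"S",0,0,10,75
"C","C-011",1,68,"S",1,1,10.5,100
"C","C-011",2,69,"S",1,1,10.5,100
"B","B-016",1,70,"S",0,0,6.5,200
"B","B-016",2,71,"S",0,0,6.5,200
"A","A-015",1,72,"S",0,0,4,150
"B","B-017",1,73,"S",0,1,7,100
"B","B-017",2,74,"S",0,1,7,100
"A","A-016",1,75,"S",0,1,6.5,200
"A","A-016",2,76,"S",0,1,6.5,200
"A","A-017",1,77,"S",0,1,14,100
"C","C-012",1,78,"S",0,0,5,75
"B","B-018",1,79,"S",0,0,11.5,100
"B","B-018",2,80,"S",0,0,11.5,100
"B","B-018",3,81,"S",0,0,11.5,100
"B","B-019",1,82,"S",0,0,10,125
"B","B-019",2,83,"S",0,0,10,125
"C","C-013",1,84,"S",1,1,10.5,225
"A","A-018",1,85,"S",1,1,8.5,100
"A","A-018",2,86,"S",1,1,8.5,100
"B","B-020",1,87,"S",0,0,8.5,75
"B","B-020",2,88,"S",0,0,8.5,75
"B","B-020",3,89,"S",0,0,8.5,75
"C","C-014",1,90,"S",1,0,6,100
"A","A-019",1,91,"S",0,1,12.5,150
"A","A-019",2,92,"S",0,1,12.5,150
"B","B-021",1,93,"S",0,1,5.5,125
"A","A-020",1,94,"S",0,1,12,125
"C","C-015",1,95,"S",0,0,4.5,150
"C","C-015",2,96,"S",0,0,4.5,150
"A","A-021",1,97,"S",1,0,7.5,125
"B","B-022",1,98,"S",0,1,3,150
"B","B-022",2,99,"S",0,1,3,150
"A","A-022",1,100,"S",1,1,6.5,150
"A","A-022",2,101,"S",1,1,6.5,150
"B","B-023",1,102,"S",1,1,10.5,150
"B","B-023",2,103,"S",1,1,10.5,150
"C","C-016",1,104,"S",1,1,7,75
"B","B-024",1,105,"S",0,0,11,75
"C","C-017",1,106,"S",0,1,6,100
"A","A-023",1,107,"S",0,1,9,100
"B","B-025",1,108,"S",1,1,7.5,100
"B","B-025",2,109,"S",1,1,7.5,100
"B","B-025",3,110,"S",1,1,7.5,100
"A","A-024",1,111,"S",0,1,12,75
"A","A-024",2,112,"S",0,1,12,75
"B","B-026",1,113,"S",0,1,4.5,200
"C","C-018",1,114,"S",0,0,8.5,100
"A","A-025",1,115,"S",0,1,9.5,75
"B","B-027",1,116,"S",1,0,7,200
"B","B-027",2,117,"S",1,0,7,200
"C","C-019",1,118,"S",0,1,9,175
"C","C-019",2,119,"S",0,1,9,175
"B","B-028",1,120,"S",0,0,5.5,125
"B","B-028",2,121,"S",0,0,5.5,125
"A","A-026",1,122,"S",0,1,6.5,75
"B","B-029",1,123,"S",0,1,8,100
"B","B-029",2,124,"F",0,1,8,100
"A","A-027",1,125,"S",0,1,9,150
"A","A-027",2,126,"S",0,1,9,150
"A","A-027",3,127,"S",0,1,9,150
"C","C-020",1,128,"S",0,0,12,175
"C","C-020",2,129,"S",0,0,12,175
"A","A-028",1,130,"S",0,0,9.5,350
"A","A-028",2,131,"S",0,0,9.5,350
"A","A-028",3,132,"S",0,0,9.5,350
"B","B-030",1,133,"S",0,1,10,50
"B","B-030",2,134,"F",0,1,10,50
"B","B-031",1,135,"S",1,0,3,200
"A","A-029",1,136,"S",1,0,17,100
"A","A-029",2,137,"S",1,0,17,100
"C","C-021",1,138,"S",1,1,5.5,200
"C","C-021",2,139,"S",1,1,5.5,200
"A","A-030",1,140,"S",0,1,11.5,125
"B","B-032",1,141,"S",0,1,8,175
"B","B-032",2,142,"F",0,1,8,175
"C","C-022",1,143,"S",0,0,11,50
"B","B-033",1,144,"S",0,0,8,125
"A","A-031",1,145,"S",0,1,10.5,50
"C","C-023",1,146,"S",0,0,7,75
"A","A-032",1,147,"S",1,1,9.5,125
"A","A-032",2,148,"S",1,1,9.5,125
"B","B-034",1,149,"S",0,1,12,225
"B","B-034",2,150,"S",0,1,12,225
"A","A-033",1,151,"S",0,1,9,100
"A","A-033",2,152,"S",0,1,9,100
"B","B-035",1,153,"F",0,0,7.5,125
"B","B-035",2,154,"F",0,0,7.5,125
"C","C-024",1,155,"S",0,1,4.5,50
"B","B-036",1,156,"S",1,0,9,100
"C","C-025",1,157,"F",0,1,9,125
"A","A-034",1,158,"S",1,1,14,125
"B","B-037",1,159,"S",0,0,11.5,125
"A","A-035",1,160,"S",0,1,5.5,125
"C","C-026",1,161,"F",0,1,10,150
"C","C-026",2,162,"F",0,1,10,150
"B","B-038",1,163,"F",0,1,4.5,100
"B","B-038",2,164,"S",0,1,4.5,100
"B","B-038",3,165,"S",0,1,4.5,100
"A","A-036",1,166,"F",0,1,11,125
"A","A-036",2,167,"F",0,1,11,125
"B","B-039",1,168,"S",0,1,9.5,275
"C","C-027",1,169,"S",0,1,9.5,125
"C","C-027",2,170,"S",0,1,9.5,125
"B","B-040",1,171,"S",1,1,4.5,100
"B","B-040",2,172,"S",1,1,4.5,100
"A","A-037",1,173,"F",0,1,5,175
"A","A-037",2,174,"S",0,1,5,175
"A","A-038",1,175,"S",0,1,5.5,225
"A","A-038",2,176,"S",0,1,5.5,225
"B","B-041",1,177,"S",0,1,9,125
"C","C-028",1,178,"S",0,1,6,225
"A","A-039",1,179,"S",0,1,7,150
"A","A-039",2,180,"S",0,1,7,150
"A","A-040",1,181,"S",0,1,5,225
"C","C-029",1,182,"S",0,1,6.5,175
"C","C-029",2,183,"S",0,1,6.5,175
"C","C-029",3,184,"S",0,1,6.5,175
"B","B-042",1,185,"S",1,0,4,125
"B","B-043",1,186,"S",0,1,8.5,125
"B","B-043",2,187,"S",0,1,8.5,125
"A","A-041",1,188,"S",0,1,8.5,150
"A","A-041",2,189,"S",0,1,8.5,150
"A","A-041",3,190,"S",0,1,8.5,150
"B","B-044",1,191,"S",1,0,11,125
"B","B-044",2,192,"S",1,0,11,125
"C","C-030",1,193,"S",0,0,3,150
"C","C-030",2,194,"S",0,0,3,150
"A","A-042",1,195,"S",0,0,8.5,125
"A","A-042",2,196,"S",0,0,8.5,125
"B","B-045",1,197,"S",1,0,9,150
"B","B-045",2,198,"S",1,0,9,150
"B","B-045",3,199,"S",1,0,9,150
"C","C-031",1,200,"S",1,0,11,100
"A","A-043",1,201,"S",1,1,6.5,75
"A","A-043",2,202,"S",1,1,6.5,75
"B","B-046",1,203,"S",1,1,8,225
"B","B-046",2,204,"S",1,1,8,225
"C","C-032",1,205,"S",1,1,8,100
"C","C-032",2,206,"S",1,1,8,100
"B","B-047",1,207,"S",1,0,6.5,225
"A","A-044",1,208,"S",0,0,6,125
"A","A-044",2,209,"S",0,0,6,125
"A","A-044",3,210,"S",0,0,6,125
"B","B-048",1,211,"S",0,0,4.5,225
"B","B-048",2,212,"S",0,0,4.5,225
"A","A-045",1,213,"S",1,0,4.5,100
"A","A-045",2,214,"S",1,0,4.5,100
"C","C-033",1,215,"S",1,1,10,175
"A","A-046",1,216,"S",0,0,9.5,125
"B","B-049",1,217,"S",1,1,9,100
"A","A-047",1,218,"S",1,1,7.5,150
"A","A-047",2,219,"S",1,1,7.5,150
"A","A-047",3,220,"S",1,1,7.5,150
"B","B-050",1,221,"S",0,0,5.5,75
"C","C-034",1,222,"S",0,0,10,150
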