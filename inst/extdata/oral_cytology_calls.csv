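slide_number,study_id,age,sex,clinical_diagnosis,site,histology_call,cytology_call,rater1_call,rater2_call
1,CS016,42,F,Carcinoma,buccal mucosa,positive,positive,negative,positive
2,CS018,51,M,Carcinoma,tongue,positive,positive,positive,positive
3,CS003,42,M,Carcinoma,retromolar trigone,positive,positive,negative,negative
4,CS010,50,M,Carcinoma,alveolus,positive,positive,negative,positive
5,CS012,65,F,Carcinoma,tongue,positive,positive,negative,positive
6,CS014,36,M,Carcinoma,tongue,positive,positive,positive,positive
7,CS013,62,F,Carcinoma,buccal mucosa,positive,positive,positive,positive
8,CS021,72,M,Carcinoma,buccal mucosa,positive,positive,positive,positive
9,CS031,35,M,Carcinoma,buccal mucosa,positive,positive,positive,positive
10,CS032,62,M,Carcinoma,buccal mucosa,positive,positive,positive,positive
11,CS033,49,M,Carcinoma,buccal mucosa,positive,positive,positive,positive
12,CS034,53,M,Carcinoma,buccal mucosa,positive,positive,positive,positive
13,CS035,47,M,Carcinoma,tongue,positive,positive,positive,positive
14,CS037,44,F,Carcinoma,buccal mucosa,positive,positive,positive,positive
15,CS041,34,M,Carcinoma,tongue,positive,negative,negative,negative
16,CS044,67,M,Carcinoma,tongue,positive,positive,positive,positive
17,CS045,60,F,Carcinoma,labial mucosa,positive,positive,positive,positive
18,CS051,62,M,Carcinoma,tongue,positive,positive,positive,positive
19,CS002,44,M,Carcinoma,buccal mucosa,negative,negative,negative,negative
20,CS020,41,M,Tobacco pouch keratosis,buccal mucosa,positive,negative,negative,negative
21,CS022,52,M,Erythroplakia,buccal mucosa,positive,negative,negative,negative
22,CS001,61,M,Proliferative Veruccous Leukoplakia,buccal mucosa,positive,positive,negative,negative
23,CS005,23,M,Homogenous leukoplakia,buccal mucosa,positive,negative,negative,negative
24,CS008,48,M,Homogenous leukoplakia,buccal mucosa,positive,negative,negative,negative
25,CS011,65,M,Homogenous leukoplakia,buccal mucosa,positive,positive,negative,positive
26,CS019,37,M,Homogenous leukoplakia,labial mucosa,positive,negative,negative,negative
27,CS023,61,F,Reticular Lichen Planus,buccal mucosa,positive,negative,negative,negative
28,CS036,60,M,Tobacco pouch keratosis,buccal mucosa,negative,negative,negative,negative
29,CS038,64,F,Veruccous leukoplakia,buccal mucosa,positive,positive,negative,positive
30,CS039,38,M,Homogenous leukoplakia,buccal mucosa,positive,negative,negative,negative
31,CS042,65,F,Verroucous leukoplakia,buccal mucosa,positive,positive,positive,positive
32,CS043,28,M,Tobacco pouch keratosis,buccal mucosa,positive,negative,negative,negative
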